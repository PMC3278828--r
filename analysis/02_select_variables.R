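#!/usr/bin/env Rscript
# Step 2 — variable selection, three ways.
#
# Stepwise regression picks the linear model's inputs; network sensitivity
# analysis with backward elimination prunes the recurrent net's (and hence
# the fuzzy model's) inputs; the evolutionary model's GA mask is exercised
# at training time (step 3). Run analysis/01_simulate.R first.

library(limnocast)

series <- read_series_csv("results/series.csv")
split <- split_series(series, c(0.6, 0.2, 0.2), "contiguous", seed = 1)
spec <- fit_normalizer(split$train_A)
norm_split <- structure(list(
  train_A = apply_normalizer(spec, split$train_A),
  test_B = apply_normalizer(spec, split$test_B),
  validate_C = apply_normalizer(spec, split$validate_C)),
  class = "limno_split")

sw <- stepwise_fit(split$train_A, limno_variables())
cat("Stepwise regression selected:", paste(sw$selected, collapse = ", "),
    "\n")
print(sw)

cfg <- rann_config(6, seed = 2, max_epochs = 1200, patience = 200,
                   epoch_size = 10)
elim <- backward_eliminate(norm_split,
                           c("WaterTemp", "pH", "DO", "Secchi", "NH3N",
                             "NO3N"), cfg, tol = 0.01)
cat("Backward elimination kept:", paste(elim$selected, collapse = ", "),
    "\n")
sens <- sensitivity_analysis(elim$model, norm_split$train_A)
cat("Sensitivity ranking of the retained inputs:\n")
print(sens, row.names = FALSE)

write.csv(rbind(
  data.frame(method = "stepwise", variables = paste(sw$selected,
                                                    collapse = "+")),
  data.frame(method = "backward_elimination",
             variables = paste(elim$selected, collapse = "+"))),
  "results/variable_selection.csv", row.names = FALSE)
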