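# End-to-end comparative study: simulate (or load) a limnological series,
# split it into sets A/B/C, train the four model families on A (with C for
# early stopping where needed), and assess them all on B with the common
# RMSE / r / AUC criteria.

#' Configuration of the comparative study
#'
#' Exactly one data source: a [synth_config()] or a CSV path. Per-stage
#' seeds are derived from `seed` so individual stages can be re-run in
#' isolation.
#'
#' @param synth A [synth_config()] describing the simulated scenario, or
#'   `NULL` when reading from `csv_path`.
#' @param csv_path Input CSV (see [read_series_csv()]), or `NULL`.
#' @param fractions,split_mode Passed to [split_series()].
#' @param boundary Trophic boundary for the AUC dichotomization, ug/l.
#' @param variables_nn Input variables for the recurrent-network and fuzzy
#'   models (default: the six sensitivity-selected variables — water
#'   temperature, pH, dissolved oxygen, Secchi depth and the two nitrogen
#'   species).
#' @param candidates_mlr Candidate variables for stepwise regression
#'   (default: all ten).
#' @param candidates_hea Candidate variables for the evolutionary model
#'   (default: pH, Secchi depth, dissolved oxygen, nitrate nitrogen).
#' @param run_selection Re-derive `variables_nn` by network sensitivity
#'   analysis with backward elimination instead of using the preset list.
#' @param rann RANN hyperparameters: a [rann_config()] sized later to
#'   `length(variables_nn)` inputs (only the non-geometry fields are used),
#'   or `NULL` for defaults.
#' @param hea An [hea_config()]; default is the scaled profile.
#' @param fuzzy_grid,fuzzy_k SOM grid and label count of the fuzzy model.
#' @param seed Master seed.
#' @param outdir Optional directory; when set, models, predictions, the ROC
#'   curves and the report are written there as CSV/JSON-like text files.
#' @return A `study_config` list.
#' @export
study_config <- function(synth = synth_config(n = 400),
                         csv_path = NULL,
                         fractions = c(0.6, 0.2, 0.2),
                         split_mode = "contiguous",
                         boundary = 8.0,
                         variables_nn = c("WaterTemp", "pH", "DO", "Secchi",
                                          "NH3N", "NO3N"),
                         candidates_mlr = limno_variables(),
                         candidates_hea = c("pH", "Secchi", "DO", "NO3N"),
                         run_selection = FALSE,
                         rann = NULL, hea = NULL,
                         fuzzy_grid = c(6, 6), fuzzy_k = 3,
                         seed = 1L, outdir = NULL) {
  if (is.null(synth) == is.null(csv_path)) {
    stop("specify exactly one data source (synth or csv_path)")
  }
  if (is.null(hea)) hea <- hea_config_scaled(seed = seed)
  structure(as.list(environment()), class = "study_config")
}

#' Run the four-model comparative study
#'
#' Pipeline: data (simulated or read) -> A/B/C split -> normalization
#' fitted on A -> stepwise MLR, fuzzy-logic, recurrent-network and
#' evolutionary models trained on A (C for early stopping / validation) ->
#' all four assessed on B at the configured trophic boundary. Fully
#' reproducible from the configuration and master seed.
#'
#' @param config A [study_config()].
#' @return A `study_result`: `report` (four rows — MLR, FL, RANN, HEA — with
#'   RMSE, r, AUC, grade), `models`, `predictions`, `split`, `normalizer`,
#'   and `roc` curves per model.
#' @export
compare_models <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  stage <- "data"
  result <- tryCatch({
    series <- if (!is.null(config$synth)) generate_series(config$synth)
              else read_series_csv(config$csv_path)
    stage <- "split"
    split <- split_series(series, config$fractions, config$split_mode,
                          seed = derive_seed(config$seed, "split"))
    stage <- "normalize"
    spec <- fit_normalizer(split$train_A)
    norm_split <- list(train_A = apply_normalizer(spec, split$train_A),
                       test_B = apply_normalizer(spec, split$test_B),
                       validate_C = apply_normalizer(spec,
                                                     split$validate_C))

    rann_cfg <- function(n_inputs) {
      base <- config$rann
      if (is.null(base)) {
        rann_config(n_inputs, seed = derive_seed(config$seed, "rann"),
                    max_epochs = 400, patience = 40)
      } else {
        base$n_inputs <- as.integer(n_inputs)
        base
      }
    }

    variables_nn <- config$variables_nn
    selection <- NULL
    if (config$run_selection) {
      stage <- "variable selection"
      norm_split_cls <- norm_split
      class(norm_split_cls) <- "limno_split"
      selection <- backward_eliminate(norm_split_cls, variables_nn,
                                      rann_cfg(length(variables_nn)))
      variables_nn <- selection$selected
    }

    stage <- "MLR"
    mlr_fit <- stepwise_fit(split$train_A, config$candidates_mlr)

    stage <- "FL"
    fl_fit <- fuzzy_fit(split$train_A, variables_nn, spec = spec,
                        grid = config$fuzzy_grid, k = config$fuzzy_k,
                        seed = derive_seed(config$seed, "fl"))

    stage <- "RANN"
    cfg_r <- rann_cfg(length(variables_nn))
    rann_fit <- rann_init(cfg_r, variables_nn)
    rann_fit <- rann_train(rann_fit, norm_split$train_A,
                           norm_split$validate_C, cfg_r)

    stage <- "HEA"
    hea_cfg <- config$hea
    hea_cfg$seed <- derive_seed(config$seed, "hea")
    hea_fit <- hea_run(split, config$candidates_hea, hea_cfg)

    stage <- "evaluation"
    predictors <- list(
      MLR = function(s) mlr_predict(mlr_fit, s),
      FL = function(s) fuzzy_predict(fl_fit, s),
      RANN = function(s) rann_predict(rann_fit, s, spec),
      HEA = function(s) eval_rule(hea_fit$best, s))
    report <- do.call(rbind, lapply(names(predictors), function(nm) {
      evaluate_model(predictors[[nm]], split$test_B, config$boundary, nm)
    }))
    roc <- lapply(predictors, function(fn) {
      tryCatch(roc_auc(split$test_B$chla, fn(split$test_B),
                       config$boundary), error = function(e) NULL)
    })
    predictions <- data.frame(index = split$test_B$index,
                              observed = split$test_B$chla)
    for (nm in names(predictors)) {
      predictions[[nm]] <- predictors[[nm]](split$test_B)
    }
    structure(list(report = report, models = list(mlr = mlr_fit,
                                                  fl = fl_fit,
                                                  rann = rann_fit,
                                                  hea = hea_fit),
                   predictions = predictions, split = split,
                   normalizer = spec, roc = roc, selection = selection,
                   config = config),
              class = "study_result")
  }, error = function(e) {
    stop("comparative study failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  if (!is.null(config$outdir)) {
    write_study_result(result, config$outdir)
  }
  result
}

#' @export
print.study_result <- function(x, ...) {
  cat("Comparative chlorophyll-a model assessment (test set B, n = ",
      x$report$n[1], ")\n", sep = "")
  rep <- x$report
  rep$rmse <- sprintf("%.2f", rep$rmse)
  rep$r <- sprintf("%.2f", rep$r)
  rep$auc <- sprintf("%.2f", rep$auc)
  print.data.frame(rep[, c("model", "rmse", "r", "auc", "auc_grade")],
                   row.names = FALSE)
  invisible(x)
}

#' Write study artifacts to a directory
#'
#' Emits the comparison report, per-model test-set predictions and ROC
#' curve points as CSV files.
#'
#' @param result A `study_result`.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, `outdir`.
#' @export
write_study_result <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$report, file.path(outdir, "report.csv"),
                   row.names = FALSE)
  utils::write.csv(result$predictions,
                   file.path(outdir, "predictions_test_B.csv"),
                   row.names = FALSE)
  for (nm in names(result$roc)) {
    if (!is.null(result$roc[[nm]])) {
      utils::write.csv(result$roc[[nm]]$points,
                       file.path(outdir, paste0("roc_", nm, ".csv")),
                       row.names = FALSE)
    }
  }
  writeLines(c(format_rule(result$models$hea$best),
               paste("# best test RMSE:",
                     signif(result$models$hea$best_test_rmse, 6))),
             file.path(outdir, "hea_best_rule.txt"))
  invisible(outdir)
}
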