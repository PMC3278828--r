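Package: limnocast
Title: Comparative Chlorophyll-a Prediction Models for Tropical Lakes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A comparative modelling workbench for forecasting chlorophyll-a
    concentration from routine limnological measurements. Implements four
    model families side by side: stepwise multiple linear regression, a
    Mamdani fuzzy-logic model built from self-organizing-map clusters, an
    Elman-style recurrent neural network trained by backpropagation through
    time with momentum, and a hybrid evolutionary algorithm that discovers
    IF-THEN-ELSE predictive rules by genetic programming and refines their
    constants with a genetic algorithm. Models are assessed on a common
    three-criterion scale (RMSE, Pearson correlation, and trophic-state
    dichotomized ROC/AUC). A synthetic-data generator emulating tropical
    lake water-quality series makes the whole pipeline testable end to end.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
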