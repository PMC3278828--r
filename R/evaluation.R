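# Three-criterion model assessment: RMSE on the original chlorophyll-a
# scale, Pearson correlation with a reliability flag at r >= 0.5, and ROC
# analysis after dichotomizing observed chlorophyll-a at a trophic boundary,
# with the area obtained by the trapezoidal rule.

#' Root mean square error
#'
#' `sqrt(mean((y - yhat)^2))` over paired observed and predicted values.
#'
#' @param observed,predicted Equal-length finite numeric vectors.
#' @return RMSE, same units as the inputs (ug/l for chlorophyll-a).
#' @export
rmse <- function(observed, predicted) {
  if (length(observed) == 0 || length(observed) != length(predicted)) {
    stop("observed and predicted must be non-empty and of equal length")
  }
  if (any(!is.finite(observed)) || any(!is.finite(predicted))) {
    stop("non-finite values in input")
  }
  sqrt(mean((observed - predicted)^2))
}

#' Pearson correlation with reliability flag
#'
#' Product-moment correlation between observations and predictions. A model
#' is conventionally considered reliable when r >= 0.5; that flag is
#' attached as attribute `"reliable"`.
#'
#' @param observed,predicted Numeric vectors, length >= 2, neither constant.
#' @return Correlation coefficient with attribute `reliable`.
#' @export
pearson_r <- function(observed, predicted) {
  if (length(observed) < 2 || length(observed) != length(predicted)) {
    stop("need equal-length vectors of length >= 2")
  }
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0) {
    stop("correlation undefined: constant input vector")
  }
  r <- stats::cor(observed, predicted)
  attr(r, "reliable") <- r >= 0.5
  r
}

#' ROC curve and trapezoidal AUC for dichotomized chlorophyll-a
#'
#' Observations are labelled positive when observed chlorophyll-a is at or
#' above `positive_boundary` (default 8 ug/l, the mesotrophic/eutrophic
#' divide). The curve is traced by sweeping a decision threshold over every
#' distinct predicted value (plus an all-negative endpoint); tied scores
#' contribute single diagonal segments. The area is the trapezoidal sum,
#' equivalent to the Mann-Whitney rank statistic with ties counted half.
#'
#' @param observed_chla Observed chlorophyll-a, ug/l.
#' @param scores Predicted chlorophyll-a (any monotone score works).
#' @param positive_boundary Dichotomization boundary, ug/l.
#' @return A `roc_curve`: list with `points` (data frame `fpr`, `tpr`),
#'   `auc`, and `positive_boundary`.
#' @export
roc_auc <- function(observed_chla, scores, positive_boundary = 8.0) {
  if (length(observed_chla) != length(scores) || length(scores) == 0) {
    stop("observed and scores must be non-empty and of equal length")
  }
  labels <- observed_chla >= positive_boundary
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("degenerate classification: all samples on one side of ",
         positive_boundary, " ug/l")
  }
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  # collapse tied scores into single steps
  grp <- cumsum(!duplicated(sc))
  tp <- c(0, cumsum(tapply(lab, grp, sum)))
  fp <- c(0, cumsum(tapply(!lab, grp, sum)))
  points <- data.frame(fpr = unname(fp) / n_neg, tpr = unname(tp) / n_pos)
  auc <- sum(diff(points$fpr) * (utils::head(points$tpr, -1) +
                                   utils::tail(points$tpr, -1)) / 2)
  structure(list(points = points, auc = auc,
                 positive_boundary = positive_boundary),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC = %.4f (boundary %.2f ug/l, %d vertices)\n",
              x$auc, x$positive_boundary, nrow(x$points)))
  invisible(x)
}

#' Grade an AUC value
#'
#' Discrimination grades: `outstanding` above 0.9, `excellent` for
#' 0.8-0.9, `acceptable` for 0.7-0.8, otherwise `poor`.
#'
#' @param auc Area under the ROC curve, in \[0, 1\].
#' @return One of `"outstanding"`, `"excellent"`, `"acceptable"`, `"poor"`.
#' @export
grade_auc <- function(auc) {
  if (any(auc < 0 | auc > 1)) stop("auc must lie in [0, 1]")
  vapply(auc, function(a) {
    if (a > 0.9) "outstanding"
    else if (a >= 0.8) "excellent"
    else if (a >= 0.7) "acceptable"
    else "poor"
  }, character(1))
}

#' Assemble the three assessment criteria for one model
#'
#' Computes RMSE, Pearson r and dichotomized AUC of a predictor on a test
#' series, on the original (ug/l) chlorophyll-a scale. A degenerate
#' correlation (constant predictions) or a one-class AUC is reported as `NA`
#' with a warning rather than aborting, so RMSE is still comparable.
#'
#' @param predict_fn Function mapping a [limno_series()] to a numeric vector
#'   of chlorophyll-a predictions (ug/l).
#' @param test Test [limno_series()] with observed `chla`.
#' @param boundary Trophic boundary for the ROC dichotomization, ug/l.
#' @param model_name Label for the report row.
#' @return One-row data frame: `model`, `rmse`, `r`, `auc`, `auc_grade`, `n`.
#' @export
evaluate_model <- function(predict_fn, test, boundary = 8.0,
                           model_name = "model") {
  if (nrow(test) == 0) stop("empty test series")
  pred <- predict_fn(test)
  if (length(pred) != nrow(test)) {
    stop("predictor returned ", length(pred), " values for ", nrow(test),
         " samples")
  }
  if (any(!is.finite(pred))) {
    bad <- which(!is.finite(pred))[1]
    stop("non-finite prediction at sample index ", test$index[bad])
  }
  obs <- test$chla
  rmse_v <- rmse(obs, pred)
  r_v <- tryCatch(as.numeric(pearson_r(obs, pred)), error = function(e) {
    warning("correlation undefined for ", model_name, ": ",
            conditionMessage(e))
    NA_real_
  })
  auc_v <- tryCatch(roc_auc(obs, pred, boundary)$auc, error = function(e) {
    warning("AUC undefined for ", model_name, ": ", conditionMessage(e))
    NA_real_
  })
  data.frame(model = model_name, rmse = rmse_v, r = r_v, auc = auc_v,
             auc_grade = if (is.na(auc_v)) NA_character_ else grade_auc(auc_v),
             n = nrow(test), stringsAsFactors = FALSE)
}
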