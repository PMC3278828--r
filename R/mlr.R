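# Stepwise multiple linear regression for chlorophyll-a: forward selection
# on partial p-values with drop-out of variables that lose significance as
# others enter (the classic stepwise procedure, p-to-enter 0.05 and
# p-to-remove 0.10). Fitting is ordinary least squares via stats::lm on the
# original measurement units.

# p-values of the non-intercept coefficients of an lm fit; a numerically
# perfect fit (zero residual variance) yields NaN t statistics, which we
# treat as p = 0 for any non-null coefficient.
coef_pvalues <- function(fit) {
  sm <- summary(fit)$coefficients
  p <- stats::setNames(sm[-1, 4], rownames(sm)[-1])
  est <- stats::setNames(sm[-1, 1], rownames(sm)[-1])
  nan <- is.nan(p)
  p[nan & abs(est) > 1e-10] <- 0
  p[nan & abs(est) <= 1e-10] <- 1
  p
}

#' Stepwise regression for chlorophyll-a
#'
#' Iterates: add the candidate with the smallest partial p-value below
#' `entry_alpha` (ties broken by candidate order), then drop any included
#' variable whose p-value exceeds `removal_alpha`; stops when neither step
#' changes the model. Candidates whose entry would make the design singular
#' (aliased coefficients) are skipped, so duplicated predictors cannot crash
#' the fit. If nothing ever enters, an intercept-only model is returned with
#' a warning.
#'
#' @param train Training [limno_series()] with `chla`.
#' @param candidates Candidate predictor names (default: all series
#'   variables).
#' @param entry_alpha,removal_alpha Significance thresholds;
#'   `removal_alpha >= entry_alpha`.
#' @return An `mlr_model`: intercept, named coefficient vector, `selected`
#'   (entry order), the thresholds, and final per-variable p-values.
#' @export
stepwise_fit <- function(train, candidates = NULL, entry_alpha = 0.05,
                         removal_alpha = 0.10) {
  if (is.null(candidates)) candidates <- series_variables(train)
  if (removal_alpha < entry_alpha) {
    stop("removal_alpha must be >= entry_alpha")
  }
  if (nrow(train) <= length(candidates) + 2) {
    stop("need more than ", length(candidates) + 2, " samples for ",
         length(candidates), " candidates")
  }
  missing_vars <- setdiff(candidates, names(train))
  if (length(missing_vars) > 0) {
    stop("candidates absent from series: ",
         paste(missing_vars, collapse = ", "))
  }
  df <- as.data.frame(train)
  selected <- character(0)
  resp_scale <- stats::sd(df$chla)
  repeat {
    changed <- FALSE
    # forward step -- skipped once the current model fits perfectly
    # (no candidate can significantly reduce a zero residual variance)
    cur <- stats::lm(stats::reformulate(if (length(selected)) selected
                                        else "1", response = "chla"),
                     data = df)
    if (summary(cur)$sigma < 1e-8 * resp_scale) break
    pool <- setdiff(candidates, selected)
    entry_p <- rep(NA_real_, length(pool))
    for (i in seq_along(pool)) {
      fml <- stats::reformulate(c(selected, pool[i]), response = "chla")
      fit <- stats::lm(fml, data = df)
      if (anyNA(stats::coef(fit))) next  # singular with this candidate
      entry_p[i] <- coef_pvalues(fit)[[pool[i]]]
    }
    if (any(!is.na(entry_p)) && min(entry_p, na.rm = TRUE) < entry_alpha) {
      best <- pool[which.min(replace(entry_p, is.na(entry_p), Inf))]
      selected <- c(selected, best)
      changed <- TRUE
    }
    # backward step(s)
    repeat {
      if (length(selected) == 0) break
      fit <- stats::lm(stats::reformulate(selected, response = "chla"),
                       data = df)
      p <- coef_pvalues(fit)[selected]
      if (max(p) > removal_alpha) {
        worst <- selected[which.max(p)]
        selected <- setdiff(selected, worst)
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  if (length(selected) == 0) {
    warning("no candidate reached entry significance; ",
            "returning intercept-only model")
    fit <- stats::lm(chla ~ 1, data = df)
    coefs <- numeric(0)
    pvals <- numeric(0)
  } else {
    fit <- stats::lm(stats::reformulate(selected, response = "chla"),
                     data = df)
    coefs <- stats::coef(fit)[selected]
    pvals <- coef_pvalues(fit)[selected]
  }
  structure(list(intercept = unname(stats::coef(fit)[1]),
                 coefficients = coefs, selected = selected,
                 entry_alpha = entry_alpha, removal_alpha = removal_alpha,
                 fit_summary = pvals),
            class = "mlr_model")
}

#' Construct an MLR model from known coefficients
#'
#' Useful for evaluating a published regression line without refitting.
#'
#' @param intercept Intercept, ug/l.
#' @param coefficients Named numeric vector of slopes.
#' @return An `mlr_model`.
#' @export
mlr_model <- function(intercept, coefficients = c(DO = 2.732)) {
  structure(list(intercept = intercept, coefficients = coefficients,
                 selected = names(coefficients), entry_alpha = NA_real_,
                 removal_alpha = NA_real_, fit_summary = NULL),
            class = "mlr_model")
}

#' @export
print.mlr_model <- function(x, ...) {
  terms <- if (length(x$coefficients) == 0) "" else
    paste(sprintf(" %+.4g*%s", x$coefficients, names(x$coefficients)),
          collapse = "")
  cat(sprintf("<mlr_model> chla = %.4g%s\n", x$intercept, terms))
  invisible(x)
}

#' Predict chlorophyll-a from a linear model
#'
#' `intercept + sum(coefficient * value)`, unclamped (a linear model may
#' extrapolate below zero).
#'
#' @param model An `mlr_model`.
#' @param samples Data frame or [limno_series()] carrying every selected
#'   variable.
#' @return Numeric vector of predictions, ug/l.
#' @export
mlr_predict <- function(model, samples) {
  samples <- as.data.frame(samples)
  need <- setdiff(names(model$coefficients), names(samples))
  if (length(need) > 0) {
    stop("samples lack selected variable(s): ", paste(need, collapse = ", "))
  }
  out <- rep(model$intercept, nrow(samples))
  for (v in names(model$coefficients)) {
    out <- out + model$coefficients[[v]] * samples[[v]]
  }
  out
}
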