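# Synthetic limnological series emulating a shallow tropical lake record:
# marginals bounded by per-variable (min, mean, max) summaries, rank
# correlation induced through a Gaussian copula, optional AR(1) temporal
# persistence, and a planted chlorophyll-generating mechanism plus noise.

#' Per-variable summary table used as generator defaults
#'
#' Minimum, average and maximum of each water-quality variable in a shallow
#' oligo-mesotrophic tropical reservoir, plus chlorophyll-a (ug/l). These
#' triples parameterize the scaled-Beta marginals of [generate_series()].
#'
#' @return Data frame with columns `variable`, `min`, `mean`, `max`.
#' @export
synth_variable_table <- function() {
  data.frame(
    variable = c(limno_variables(), "chla"),
    min  = c(28.42, 6.16, 5.72, 0.30,  3.50,  60.00, 0.00, 0.00,  2.00,  0.00, 0.00),
    mean = c(30.29, 7.40, 7.41, 1.03, 13.68,  92.52, 0.05, 1.18, 18.61,  4.88, 7.28),
    max  = c(32.33, 8.44, 9.08, 1.75, 53.10, 189.00, 0.53, 4.82, 79.00, 46.00, 31.70),
    stringsAsFactors = FALSE)
}

#' Default target rank-correlation matrix among predictors
#'
#' A declared assumption (no correlations are published for the emulated
#' record): moderate positive association within the temperature/oxygen/pH
#' block and the particulate block (turbidity, TSS, COD), negative
#' transparency-turbidity association, and mild coupling of the nitrogen
#' species. Verified positive definite.
#'
#' @return 10 x 10 symmetric correlation matrix (Spearman targets).
#' @export
default_correlation <- function() {
  v <- limno_variables()
  R <- diag(length(v))
  dimnames(R) <- list(v, v)
  set_r <- function(a, b, r) {
    R[a, b] <<- r
    R[b, a] <<- r
  }
  set_r("DO", "pH", 0.6)
  set_r("DO", "WaterTemp", 0.4)
  set_r("pH", "WaterTemp", 0.3)
  set_r("Secchi", "Turbidity", -0.6)
  set_r("Secchi", "TSS", -0.4)
  set_r("Turbidity", "TSS", 0.5)
  set_r("COD", "TSS", 0.3)
  set_r("NH3N", "NO3N", 0.4)
  R
}

#' Planted chlorophyll-generating mechanisms
#'
#' `mechanism_linear_do()` is chla = intercept + slope * DO;
#' `mechanism_mlr_printed()` fixes the coefficients to -11.685 and 2.732
#' (the stepwise-regression line recovered in the comparative study this
#' package emulates); `mechanism_hea_printed()` is the published best
#' evolved IF-THEN-ELSE rule over NO3N, Secchi, DO and pH; `mechanism_rule()`
#' plants any [rule_set()] (or rule text).
#'
#' @param intercept,slope Coefficients of the linear mechanism (ug/l and
#'   ug/l per mg/l DO).
#' @param ruleset A [rule_set()] or rule text for [parse_rule()].
#' @return A `limno_mechanism` object, evaluable with [eval_mechanism()].
#' @name mechanisms
NULL

#' @rdname mechanisms
#' @export
mechanism_linear_do <- function(intercept = -11.685, slope = 2.732) {
  structure(list(kind = "linear_do", intercept = intercept, slope = slope),
            class = "limno_mechanism")
}

#' @rdname mechanisms
#' @export
mechanism_mlr_printed <- function() {
  m <- mechanism_linear_do(-11.685, 2.732)
  m$kind <- "printed_mlr_line"
  m
}

PRINTED_HEA_RULE_TEXT <- paste0(
  "IF ((((NO3N*126.117)>=5.273)OR(Secchi>154.513))",
  "AND(((NO3N*444.685)*(NO3N*13.361))<444.685)) ",
  "THEN chlorophyll-a=(96.579/DO) ",
  "ELSE chlorophyll-a=(DO-ln(|((61.273/pH)-DO)|))")

#' @rdname mechanisms
#' @export
mechanism_hea_printed <- function() {
  structure(list(kind = "printed_hea_rule",
                 ruleset = parse_rule(PRINTED_HEA_RULE_TEXT)),
            class = "limno_mechanism")
}

#' @rdname mechanisms
#' @export
mechanism_rule <- function(ruleset) {
  if (is.character(ruleset)) ruleset <- parse_rule(ruleset)
  stopifnot(inherits(ruleset, "rule_set"))
  structure(list(kind = "custom_rule", ruleset = ruleset),
            class = "limno_mechanism")
}

#' Evaluate a planted mechanism on samples
#'
#' Pure, noise-free evaluation of the chlorophyll-generating mechanism.
#'
#' @param mechanism A `limno_mechanism` (see [mechanisms]).
#' @param samples Data frame or [limno_series()] carrying the mechanism's
#'   input variables.
#' @return Numeric vector of noiseless chlorophyll-a values (ug/l; may be
#'   negative for linear mechanisms — [generate_series()] clamps at 0 after
#'   adding noise).
#' @export
eval_mechanism <- function(mechanism, samples) {
  stopifnot(inherits(mechanism, "limno_mechanism"))
  samples <- as.data.frame(samples)
  if (mechanism$kind %in% c("linear_do", "printed_mlr_line")) {
    if (is.null(samples$DO)) stop("mechanism requires variable 'DO'")
    mechanism$intercept + mechanism$slope * samples$DO
  } else {
    eval_rule(mechanism$ruleset, samples)
  }
}

#' Generator configuration
#'
#' @param n Number of samples (a 4-year bi-weekly record is 104).
#' @param seed Integer seed; the series is bit-identical for equal seeds.
#' @param variable_specs Data frame like [synth_variable_table()] (rows for
#'   `chla` are ignored by the marginal sampler; chla comes from the
#'   mechanism).
#' @param correlation Target Spearman correlation matrix among predictors
#'   (names must match `variable_specs`); see [default_correlation()].
#' @param mechanism Planted chlorophyll mechanism (see [mechanisms]).
#' @param noise_sd Gaussian noise added to the mechanism output, ug/l.
#' @param ar_phi AR(1) coefficient of the latent Gaussian process giving
#'   each predictor temporal persistence (0 = independent sampling).
#' @return A `synth_config` list.
#' @export
synth_config <- function(n = 104, seed = 1L,
                         variable_specs = synth_variable_table(),
                         correlation = default_correlation(),
                         mechanism = mechanism_hea_printed(),
                         noise_sd = 2.0, ar_phi = 0.5) {
  specs <- variable_specs[variable_specs$variable != "chla", , drop = FALSE]
  if (any(!(specs$min <= specs$mean & specs$mean <= specs$max))) {
    bad <- specs$variable[!(specs$min <= specs$mean & specs$mean <= specs$max)]
    stop("infeasible min/mean/max for: ", paste(bad, collapse = ", "))
  }
  if (any(specs$min >= specs$max)) {
    stop("degenerate range (min >= max) in variable_specs")
  }
  vars <- specs$variable
  correlation <- correlation[vars, vars, drop = FALSE]
  if (any(abs(correlation - t(correlation)) > 1e-12) ||
      any(abs(diag(correlation) - 1) > 1e-12)) {
    stop("correlation must be symmetric with unit diagonal")
  }
  if (min(eigen(correlation, symmetric = TRUE,
                only.values = TRUE)$values) < -1e-8) {
    stop("correlation matrix is not positive semidefinite")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (abs(ar_phi) >= 1) stop("ar_phi must lie in (-1, 1)")
  structure(list(n = n, seed = as.integer(seed), variable_specs = specs,
                 correlation = correlation, mechanism = mechanism,
                 noise_sd = noise_sd, ar_phi = ar_phi),
            class = "synth_config")
}

# Beta shapes matched to the standardized mean m = (mean-min)/(max-min),
# with the smaller shape fixed at 2 so the density is unimodal on (0, 1).
beta_shapes <- function(m) {
  m <- min(max(m, 1e-6), 1 - 1e-6)
  if (m <= 0.5) c(a = 2, b = 2 * (1 - m) / m) else c(a = 2 * m / (1 - m), b = 2)
}

#' Generate a synthetic limnological series
#'
#' Draws each predictor from a scaled Beta distribution on its configured
#' \[min, max\] with shape solved from the configured mean, couples the
#' predictors through a Gaussian copula targeting the configured Spearman
#' correlations, gives the latent Gaussian process AR(1) persistence across
#' sampling occasions, and sets
#' `chla = max(0, mechanism(sample) + N(0, noise_sd))`.
#'
#' @param config A [synth_config()].
#' @return A [limno_series()] with `chla`.
#' @export
generate_series <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  specs <- config$variable_specs
  vars <- specs$variable
  n <- config$n
  if (n == 0) {
    empty <- as.data.frame(setNames(rep(list(numeric(0)), length(vars) + 2),
                                    c("index", vars, "chla")))
    return(structure(empty, variables = vars,
                     class = c("limno_series", "data.frame")))
  }
  with_seed(config$seed, {
    # Spearman target -> Pearson correlation of the Gaussian copula
    Rz <- 2 * sin(pi * config$correlation / 6)
    diag(Rz) <- 1
    ev <- eigen(Rz, symmetric = TRUE)
    ev$values <- pmax(ev$values, 1e-10)
    L <- ev$vectors %*% diag(sqrt(ev$values))
    p <- length(vars)
    Z <- matrix(0, n, p)
    phi <- config$ar_phi
    innov_scale <- sqrt(1 - phi^2)
    z_prev <- L %*% stats::rnorm(p)
    Z[1, ] <- z_prev
    if (n > 1) {
      for (t in 2:n) {
        z_prev <- phi * z_prev + innov_scale * (L %*% stats::rnorm(p))
        Z[t, ] <- z_prev
      }
    }
    U <- stats::pnorm(Z)
    X <- matrix(0, n, p, dimnames = list(NULL, vars))
    for (j in seq_len(p)) {
      m <- (specs$mean[j] - specs$min[j]) / (specs$max[j] - specs$min[j])
      sh <- beta_shapes(m)
      X[, j] <- specs$min[j] +
        (specs$max[j] - specs$min[j]) * stats::qbeta(U[, j], sh["a"], sh["b"])
    }
    df <- as.data.frame(X)
    df$index <- seq_len(n)
    mu <- eval_mechanism(config$mechanism, df)
    df$chla <- pmax(0, mu + stats::rnorm(n, 0, config$noise_sd))
    limno_series(df, vars)
  })
}
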