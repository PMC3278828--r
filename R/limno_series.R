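#' Canonical limnological variable set
#'
#' The ten routinely measured water-quality variables used throughout the
#' package, in their canonical order: water temperature (degC), pH, dissolved
#' oxygen (mg/l), Secchi depth (m), turbidity (NTU), conductivity (uS/cm),
#' ammonia nitrogen (mg/l), nitrate nitrogen (mg/l), chemical oxygen demand
#' (mg/l) and total suspended solids (mg/l). The response, chlorophyll-a
#' (ug/l), is carried in a separate `chla` column.
#'
#' @return Character vector of the ten canonical predictor names.
#' @export
limno_variables <- function() {
  c("WaterTemp", "pH", "DO", "Secchi", "Turbidity",
    "Conductivity", "NH3N", "NO3N", "COD", "TSS")
}

#' Construct a limnological time series
#'
#' A `limno_series` is a data frame with an ordinal `index` column (sampling
#' occasion, e.g. bi-weekly visits), one column per water-quality variable,
#' and an optional `chla` response column (ug/l). Rows are kept sorted by
#' `index` and all measurements must be finite.
#'
#' @param data Data frame containing `index`, measurement columns, and
#'   optionally `chla`.
#' @param variables Character vector naming the predictor columns; defaults
#'   to the intersection of `names(data)` with [limno_variables()].
#' @return A `limno_series` object (a data frame).
#' @export
limno_series <- function(data, variables = NULL) {
  data <- as.data.frame(data)
  if (is.null(variables)) {
    variables <- intersect(limno_variables(), names(data))
  }
  if (!"index" %in% names(data)) {
    data$index <- seq_len(nrow(data))
  }
  missing_vars <- setdiff(variables, names(data))
  if (length(missing_vars) > 0) {
    stop("variables absent from data: ", paste(missing_vars, collapse = ", "))
  }
  unknown <- setdiff(variables, limno_variables())
  if (length(unknown) > 0) {
    stop("unknown variable name(s): ", paste(unknown, collapse = ", "),
         " (canonical set: ", paste(limno_variables(), collapse = ", "), ")")
  }
  keep <- c("index", variables, intersect("chla", names(data)))
  data <- data[order(data$index), keep, drop = FALSE]
  if (anyDuplicated(data$index)) {
    stop("sample index must be strictly increasing (duplicates found)")
  }
  for (v in c(variables, intersect("chla", names(data)))) {
    if (!is.numeric(data[[v]])) stop("column '", v, "' is not numeric")
    if (any(!is.finite(data[[v]]))) {
      stop("non-finite value in column '", v, "'")
    }
  }
  if ("chla" %in% names(data) && any(data$chla < 0)) {
    stop("chla must be non-negative")
  }
  rownames(data) <- NULL
  structure(data, variables = variables,
            class = c("limno_series", "data.frame"))
}

#' @export
print.limno_series <- function(x, ...) {
  cat(sprintf("<limno_series> %d samples, %d variables%s\n", nrow(x),
              length(attr(x, "variables")),
              if ("chla" %in% names(x)) " + chla" else ""))
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("... (", nrow(x) - 6, " more rows)\n", sep = "")
  invisible(x)
}

series_variables <- function(series) {
  v <- attr(series, "variables")
  if (is.null(v)) intersect(limno_variables(), names(series)) else v
}

#' Read a limnological series from CSV
#'
#' Expects a comma-separated, dot-decimal file with a header row naming a
#' subset of the canonical variables (see [limno_variables()]) plus
#' optionally `chla` and `index`. Rows with any missing required field are
#' dropped (listwise deletion) and the number dropped is reported via a
#' message.
#'
#' @param path Path to the CSV file.
#' @param dialect Optional named character vector mapping file column names
#'   to canonical names, e.g. `c("Dissolved.oxygen" = "DO")`.
#' @return A [limno_series()].
#' @export
read_series_csv <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- tryCatch(utils::read.csv(path, check.names = FALSE),
                  error = function(e) stop("unparseable CSV '", path, "': ",
                                           conditionMessage(e)))
  if (!is.null(dialect)) {
    hit <- names(raw) %in% names(dialect)
    names(raw)[hit] <- unname(dialect[names(raw)[hit]])
  }
  variables <- intersect(limno_variables(), names(raw))
  if (length(variables) == 0) {
    stop("no canonical variable columns found in ", path)
  }
  required <- c(variables, intersect("chla", names(raw)))
  complete <- stats::complete.cases(raw[, required, drop = FALSE])
  dropped <- sum(!complete)
  if (dropped > 0) {
    message(dropped, " row(s) with missing values dropped while reading ",
            path)
  }
  raw <- raw[complete, , drop = FALSE]
  if (nrow(raw) == 0) stop("no usable rows in ", path)
  if (!"index" %in% names(raw)) raw$index <- seq_len(nrow(raw))
  limno_series(raw, variables)
}

#' Write a limnological series to CSV
#'
#' @param series A [limno_series()]; must be non-empty.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_series_csv <- function(series, path) {
  if (nrow(series) == 0) stop("refusing to write an empty series")
  df <- as.data.frame(series)
  # write.csv serializes doubles at full precision (15 significant digits)
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) stop("cannot write '", path, "': ",
                              conditionMessage(e)))
  invisible(path)
}

#' Fit a [0, 1] normalizer on a training series
#'
#' Records per-variable observed minimum and maximum of the *training* data
#' only; [apply_normalizer()] then maps x to (x - min) / (max - min).
#'
#' @param series Training [limno_series()].
#' @param variables Variables to cover; defaults to the series' variables
#'   plus `chla` when present.
#' @return A `limno_normalizer` object.
#' @export
fit_normalizer <- function(series, variables = NULL) {
  if (is.null(variables)) {
    variables <- c(series_variables(series), intersect("chla", names(series)))
  }
  missing_vars <- setdiff(variables, names(series))
  if (length(missing_vars) > 0) {
    stop("variables absent from series: ",
         paste(missing_vars, collapse = ", "))
  }
  rng <- lapply(variables, function(v) {
    r <- range(series[[v]])
    if (r[2] <= r[1]) {
      stop("variable '", v, "' is constant (", r[1],
           "); cannot normalize a degenerate range")
    }
    c(min = r[1], max = r[2])
  })
  names(rng) <- variables
  structure(list(ranges = rng), class = "limno_normalizer")
}

#' @export
print.limno_normalizer <- function(x, ...) {
  cat("<limno_normalizer>\n")
  for (v in names(x$ranges)) {
    cat(sprintf("  %-12s [%g, %g]\n", v, x$ranges[[v]]["min"],
                x$ranges[[v]]["max"]))
  }
  invisible(x)
}

#' Apply (or invert) a fitted normalizer
#'
#' Forward maps each covered variable to `(x - min) / (max - min)`; inverse
#' is the exact algebraic inverse. Values outside the training range are
#' transformed by the same formula (they may leave \[0, 1\]) and a message is
#' emitted so the excursion is logged.
#'
#' @param spec A `limno_normalizer` from [fit_normalizer()].
#' @param series A [limno_series()]; every covered variable present in the
#'   series is transformed, others are left untouched.
#' @param direction `"forward"` or `"inverse"`.
#' @return The transformed series.
#' @export
apply_normalizer <- function(spec, series,
                             direction = c("forward", "inverse")) {
  direction <- match.arg(direction)
  stopifnot(inherits(spec, "limno_normalizer"))
  vars <- intersect(c(series_variables(series),
                      intersect("chla", names(series))), names(series))
  uncovered <- setdiff(vars, names(spec$ranges))
  if (length(uncovered) > 0) {
    stop("normalizer does not cover: ", paste(uncovered, collapse = ", "))
  }
  out <- series
  n_outside <- 0L
  for (v in vars) {
    r <- spec$ranges[[v]]
    if (direction == "forward") {
      z <- (series[[v]] - r["min"]) / (r["max"] - r["min"])
      n_outside <- n_outside + sum(z < 0 | z > 1)
    } else {
      z <- series[[v]] * (r["max"] - r["min"]) + r["min"]
    }
    out[[v]] <- unname(z)
  }
  if (direction == "forward" && n_outside > 0) {
    message(n_outside, " value(s) fell outside the training range ",
            "and were transformed beyond [0, 1]")
  }
  out
}

#' Normalize a numeric vector with one variable's range
#'
#' Convenience scalar/vector form of [apply_normalizer()] for a single
#' variable (used e.g. to map network outputs back to ug/l).
#'
#' @param spec A `limno_normalizer`.
#' @param variable Variable name covered by `spec`.
#' @param x Numeric vector.
#' @param direction `"forward"` or `"inverse"`.
#' @return Numeric vector.
#' @export
normalize_values <- function(spec, variable, x,
                             direction = c("forward", "inverse")) {
  direction <- match.arg(direction)
  r <- spec$ranges[[variable]]
  if (is.null(r)) stop("normalizer does not cover '", variable, "'")
  if (direction == "forward") {
    unname((x - r["min"]) / (r["max"] - r["min"]))
  } else {
    unname(x * (r["max"] - r["min"]) + r["min"])
  }
}

#' Split a series into training (A), testing (B) and validation (C) sets
#'
#' @param series A [limno_series()].
#' @param fractions Numeric triple `(a, b, c)` summing to 1; `c` may be 0
#'   (the validation set is only needed by models with early stopping).
#' @param mode `"contiguous"` keeps each set a consecutive time block
#'   (required for recurrent training); `"interleaved"` assigns samples at
#'   random but keeps time order within each set.
#' @param seed Integer seed controlling the interleaved assignment.
#' @return List with class `limno_split`: elements `train_A`, `test_B`,
#'   `validate_C` (each a `limno_series`, possibly empty data frames for
#'   zero fractions).
#' @export
split_series <- function(series, fractions = c(0.6, 0.2, 0.2),
                         mode = c("contiguous", "interleaved"), seed = 1L) {
  mode <- match.arg(mode)
  if (length(fractions) != 3 || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must be three non-negative numbers summing to 1")
  }
  if (fractions[1] <= 0 || fractions[2] < 0) {
    stop("training fraction must be positive")
  }
  n <- nrow(series)
  n_pos <- sum(fractions > 0)
  if (n < n_pos) stop("series too small to split: ", n, " sample(s)")
  n_a <- round(n * fractions[1])
  n_b <- round(n * fractions[2])
  if (fractions[3] == 0) n_b <- n - n_a
  n_c <- n - n_a - n_b
  if (min(n_a, n_b, n_c) < 0 ||
      any(c(n_a, n_b, n_c)[fractions > 0] == 0)) {
    stop("series of ", n, " samples too small for fractions ",
         paste(signif(fractions, 3), collapse = "/"))
  }
  assignment <- rep(c("A", "B", "C"), times = c(n_a, n_b, n_c))
  if (mode == "interleaved") {
    assignment <- with_seed(seed, sample(assignment))
  }
  take <- function(set) {
    sub <- as.data.frame(series)[assignment == set, , drop = FALSE]
    rownames(sub) <- NULL
    if (nrow(sub) == 0) return(sub)
    limno_series(sub, series_variables(series))
  }
  structure(list(train_A = take("A"), test_B = take("B"),
                 validate_C = take("C")),
            class = "limno_split")
}

#' @export
print.limno_split <- function(x, ...) {
  cat(sprintf("<limno_split> A: %d  B: %d  C: %d samples\n",
              nrow(x$train_A), nrow(x$test_B), nrow(x$validate_C)))
  invisible(x)
}

#' Trophic-state scale for chlorophyll-a
#'
#' Eutrophication scale used to dichotomize chlorophyll-a for ROC analysis:
#' boundaries 1.00, 2.50, 8.0 and 25.0 ug/l separating ultra-oligotrophic,
#' oligotrophic, mesotrophic, eutrophic and hypertrophic states.
#'
#' @return List with `boundaries` (ug/l) and `labels`.
#' @export
trophic_scale <- function() {
  list(boundaries = c(1.00, 2.50, 8.0, 25.0),
       labels = c("ultra-oligotrophic", "oligotrophic", "mesotrophic",
                  "eutrophic", "hypertrophic"))
}

#' Classify chlorophyll-a into a trophic state
#'
#' Boundary ties follow the printed inequality directions of the scale:
#' ultra-oligotrophic for chla <= 1.00, oligotrophic (1.00, 2.50],
#' mesotrophic (2.50, 8.0], eutrophic (8.0, 25.0) and hypertrophic for
#' chla >= 25.0 ug/l; remaining ties go to the lower state.
#'
#' @param chla Numeric vector of chlorophyll-a concentrations (ug/l),
#'   non-negative.
#' @param scale A scale from [trophic_scale()].
#' @return Character vector of state labels.
#' @export
classify_trophic <- function(chla, scale = trophic_scale()) {
  if (any(chla < 0)) stop("chla must be non-negative")
  b <- scale$boundaries
  labels <- scale$labels
  out <- character(length(chla))
  out[chla <= b[1]] <- labels[1]
  out[chla > b[1] & chla <= b[2]] <- labels[2]
  out[chla > b[2] & chla <= b[3]] <- labels[3]
  out[chla > b[3] & chla < b[4]] <- labels[4]
  out[chla >= b[4]] <- labels[5]
  out
}

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Derive a child seed from a master seed and a stage label so stages can be
# re-run in isolation; stays below 2^31.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483647)
}
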