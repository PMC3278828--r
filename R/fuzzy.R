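# Fuzzy-logic chlorophyll-a model built from data:
#   1. a self-organizing map clusters the (normalized) inputs and output
#      jointly; map nodes are agglomerated to k clusters (default 3,
#      low/medium/high) and each cluster is summarized by per-variable means
#      and 97.5% t-based confidence bands;
#   2. triangular membership functions are anchored with membership 1.0 at
#      the cluster means (shoulders at the variable range ends);
#   3. inference rules are extracted case-by-case from the training data
#      (max-membership labelling with degree-based conflict resolution);
#   4. prediction is Mamdani min-max inference with centre-of-gravity
#      defuzzification over the chlorophyll-a range.

#' Train a self-organizing map
#'
#' Classic online Kohonen training on the rows of a normalized series:
#' prototypes are initialized from randomly chosen samples, then for each
#' presented sample the best-matching unit (nearest prototype, Euclidean)
#' and its grid neighbours move toward the sample under a Gaussian
#' neighbourhood whose radius and learning rate decay exponentially over
#' the run. Deterministic for a fixed seed.
#'
#' @param data Normalized [limno_series()] (values in \[0, 1\]).
#' @param variables Columns to cluster (typically inputs plus `chla`).
#' @param grid `c(rows, cols)` of the map; `rows * cols` must not exceed
#'   the sample count.
#' @param epochs Presentation passes over the data.
#' @param alpha0 Initial learning rate.
#' @param seed Integer seed.
#' @return A `som_grid`: prototype matrix (nodes x variables), grid
#'   coordinates, and the training settings.
#' @export
train_som <- function(data, variables, grid = c(6, 6), epochs = 30,
                      alpha0 = 0.5, seed = 1L) {
  df <- as.data.frame(data)[, variables, drop = FALSE]
  n <- nrow(df)
  n_nodes <- grid[1] * grid[2]
  if (n_nodes < 2) stop("grid must have at least 2 nodes")
  if (n < n_nodes) {
    stop("fewer samples (", n, ") than map nodes (", n_nodes, ")")
  }
  X <- as.matrix(df)
  coords <- as.matrix(expand.grid(row = seq_len(grid[1]),
                                  col = seq_len(grid[2])))
  with_seed(seed, {
    proto <- X[sample.int(n, n_nodes), , drop = FALSE]
    sigma0 <- max(grid) / 2
    total <- epochs * n
    step <- 0
    for (ep in seq_len(epochs)) {
      for (i in sample.int(n)) {
        frac <- step / total
        alpha <- alpha0 * exp(-3 * frac)
        sigma <- max(sigma0 * exp(-3 * frac), 0.5)
        x <- X[i, ]
        d2 <- rowSums((proto - matrix(x, n_nodes, ncol(X),
                                      byrow = TRUE))^2)
        bmu <- which.min(d2)
        gd2 <- (coords[, 1] - coords[bmu, 1])^2 +
          (coords[, 2] - coords[bmu, 2])^2
        hfun <- alpha * exp(-gd2 / (2 * sigma^2))
        proto <- proto + hfun * (matrix(x, n_nodes, ncol(X), byrow = TRUE) -
                                   proto)
        step <- step + 1
      }
    }
    structure(list(prototypes = proto, coords = coords, grid = grid,
                   variables = variables, epochs = epochs, alpha0 = alpha0,
                   seed = seed),
              class = "som_grid")
  })
}

#' Best-matching unit of each sample
#'
#' @param grid A `som_grid`.
#' @param data Normalized data carrying the grid's variables.
#' @return Integer vector of node indices.
#' @export
som_bmu <- function(grid, data) {
  X <- as.matrix(as.data.frame(data)[, grid$variables, drop = FALSE])
  apply(X, 1, function(x) {
    which.min(colSums((t(grid$prototypes) - x)^2))
  })
}

#' Summarize map nodes as k clusters with confidence bands
#'
#' Map nodes are agglomerated to `k` clusters by hierarchical clustering
#' (Ward) of the prototypes; samples inherit the cluster of their
#' best-matching unit. Each cluster is summarized per variable by its mean
#' and a 97.5% t-based confidence band on *original-scale* values; bands of
#' adjacent clusters that intersect raise an overlap flag (a warning sign
#' that the class partition is not statistically separated). Clusters that
#' capture no samples are dropped with a warning.
#'
#' @param grid A `som_grid` trained on normalized data.
#' @param data_norm The normalized series the grid was trained on.
#' @param data_orig The same series on the original measurement scale.
#' @param k Target cluster count (>= 2; default 3 for low/medium/high).
#' @return A `cluster_summary` list: per cluster, member `count` and a
#'   per-variable data frame `mean`, `lower`, `upper`; plus an
#'   `overlap` data frame per variable.
#' @export
summarize_clusters <- function(grid, data_norm, data_orig = data_norm,
                               k = 3) {
  if (k < 2) stop("k must be >= 2")
  hc <- stats::hclust(stats::dist(grid$prototypes), method = "ward.D2")
  node_cluster <- stats::cutree(hc, k = k)
  bmu <- som_bmu(grid, data_norm)
  sample_cluster <- node_cluster[bmu]
  df <- as.data.frame(data_orig)
  present <- sort(unique(sample_cluster))
  if (length(present) < k) {
    warning(k - length(present), " cluster(s) captured no samples and were ",
            "dropped")
  }
  ci_level <- 0.975
  clusters <- lapply(present, function(cl) {
    rows <- df[sample_cluster == cl, grid$variables, drop = FALSE]
    stats_df <- do.call(rbind, lapply(grid$variables, function(v) {
      x <- rows[[v]]
      m <- mean(x)
      if (length(x) < 2 || stats::sd(x) == 0) {
        half <- 0
      } else {
        half <- stats::qt(1 - (1 - ci_level) / 2, df = length(x) - 1) *
          stats::sd(x) / sqrt(length(x))
      }
      data.frame(variable = v, mean = m, lower = m - half, upper = m + half,
                 stringsAsFactors = FALSE)
    }))
    list(id = cl, count = nrow(rows), stats = stats_df)
  })
  # overlap flags between clusters adjacent in each variable's mean order
  overlap <- do.call(rbind, lapply(grid$variables, function(v) {
    means <- vapply(clusters, function(cl)
      cl$stats$mean[cl$stats$variable == v], numeric(1))
    lo <- vapply(clusters, function(cl)
      cl$stats$lower[cl$stats$variable == v], numeric(1))
    hi <- vapply(clusters, function(cl)
      cl$stats$upper[cl$stats$variable == v], numeric(1))
    ord <- order(means)
    flags <- vapply(seq_len(length(ord) - 1), function(i) {
      hi[ord[i]] >= lo[ord[i + 1]]
    }, logical(1))
    data.frame(variable = v, pair = paste(ord[-length(ord)], ord[-1],
                                          sep = "-"),
               overlap = flags, stringsAsFactors = FALSE)
  }))
  structure(list(clusters = clusters, overlap = overlap,
                 variables = grid$variables, n = nrow(df)),
            class = "cluster_summary")
}

# ---- membership functions -------------------------------------------------

DEFAULT_FUZZY_LABELS <- c("low", "medium", "high")

fuzzy_label_names <- function(k) {
  if (k == 3) DEFAULT_FUZZY_LABELS else paste0("L", seq_len(k))
}

#' Induce triangular membership functions from cluster means
#'
#' One function per cluster, sorted by the cluster means of `variable`:
#' the peak (membership 1.0) sits at the cluster mean, the feet at the
#' neighbouring cluster means. The first and last functions are shoulders —
#' membership stays 1.0 from the peak out to the variable range end — so
#' every in-range value has positive membership and adjacent memberships
#' sum to 1 between peaks.
#'
#' @param summaries A `cluster_summary` (or a numeric vector of cluster
#'   means).
#' @param variable Variable name.
#' @param range `c(min, max)` of the variable on its original scale.
#' @return A `membership_set`: list of functions with fields `label`,
#'   `peak`, `left`, `right`, `left_shoulder`, `right_shoulder`.
#' @export
induce_memberships <- function(summaries, variable, range) {
  means <- if (is.numeric(summaries)) sort(summaries)
  else sort(vapply(summaries$clusters, function(cl)
    cl$stats$mean[cl$stats$variable == variable], numeric(1)))
  if (length(means) < 2) stop("need at least 2 clusters")
  if (any(diff(means) <= 0)) {
    stop("degenerate partition: non-distinct cluster means for '",
         variable, "'")
  }
  k <- length(means)
  labels <- fuzzy_label_names(k)
  mfs <- lapply(seq_len(k), function(i) {
    list(label = labels[i], peak = means[i],
         left = if (i == 1) range[1] else means[i - 1],
         right = if (i == k) range[2] else means[i + 1],
         left_shoulder = i == 1, right_shoulder = i == k)
  })
  structure(list(variable = variable, range = range, functions = mfs),
            class = "membership_set")
}

#' Evaluate one membership function
#'
#' @param mf A single function from a `membership_set`.
#' @param x Numeric vector.
#' @return Membership degrees in \[0, 1\]; exactly 1 at the peak.
#' @export
membership_eval <- function(mf, x) {
  out <- numeric(length(x))
  left_ok <- x <= mf$peak
  if (mf$left_shoulder) {
    out[left_ok] <- 1
  } else {
    rise <- left_ok & x >= mf$left
    out[rise] <- (x[rise] - mf$left) / (mf$peak - mf$left)
  }
  right_ok <- x > mf$peak
  if (mf$right_shoulder) {
    out[right_ok] <- 1
  } else {
    fall <- right_ok & x <= mf$right
    out[fall] <- (mf$right - x[fall]) / (mf$right - mf$peak)
  }
  pmin(pmax(out, 0), 1)
}

# Degrees of every label of a membership_set at x (vector over labels).
membership_degrees <- function(mset, x) {
  vapply(mset$functions, function(mf) membership_eval(mf, x), numeric(1))
}

# ---- rule induction -------------------------------------------------------

#' Extract inference rules from training cases
#'
#' Case-based (Wang-Mendel style) extraction: each training case votes for
#' the rule whose antecedent labels maximize the case's membership in every
#' input variable and whose consequent maximizes its chlorophyll-a
#' membership (ties take the lower label). Identical antecedents are
#' aggregated; when the same antecedent points at different consequents the
#' one with the highest summed membership-product degree wins. `support`
#' counts the cases behind the winning consequent.
#'
#' @param train Original-scale training [limno_series()] with `chla`.
#' @param memberships Named list of `membership_set`s covering every input
#'   variable and `chla`.
#' @return List of rules: `antecedent` (named label vector), `consequent`,
#'   `support`, `degree`.
#' @export
induce_rules <- function(train, memberships) {
  vars <- setdiff(names(memberships), "chla")
  df <- as.data.frame(train)
  votes <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(df))) {
    degree <- 1
    ante <- character(length(vars))
    names(ante) <- vars
    for (v in vars) {
      d <- membership_degrees(memberships[[v]], df[[v]][i])
      j <- which.max(d)
      ante[v] <- memberships[[v]]$functions[[j]]$label
      degree <- degree * d[j]
    }
    dout <- membership_degrees(memberships$chla, df$chla[i])
    jo <- which.max(dout)
    cons <- memberships$chla$functions[[jo]]$label
    degree <- degree * dout[jo]
    stopifnot(degree > 0)  # impossible by shoulder construction
    key <- paste(ante, collapse = "|")
    entry <- if (!is.null(votes[[key]])) votes[[key]]
             else list(antecedent = ante, tally = list())
    t_old <- entry$tally[[cons]]
    if (is.null(t_old)) t_old <- list(support = 0L, degree = 0)
    entry$tally[[cons]] <- list(support = t_old$support + 1L,
                                degree = t_old$degree + degree)
    votes[[key]] <- entry
  }
  rules <- lapply(ls(votes), function(key) {
    entry <- votes[[key]]
    degs <- vapply(entry$tally, function(t) t$degree, numeric(1))
    winner <- names(degs)[which.max(degs)]
    list(antecedent = entry$antecedent, consequent = winner,
         support = entry$tally[[winner]]$support,
         degree = max(degs))
  })
  rules[order(vapply(rules, function(r) -r$support, numeric(1)))]
}

# ---- model assembly and inference ----------------------------------------

#' Fit the full fuzzy-logic model
#'
#' Runs the whole pipeline: joint SOM clustering of the (normalized) inputs
#' and chlorophyll-a, agglomeration to `k` clusters with 97.5% bands,
#' per-variable membership induction anchored at the cluster means, and
#' case-based rule extraction.
#'
#' @param train Original-scale training [limno_series()] with `chla`.
#' @param variables Input variables for the model.
#' @param spec Optional `limno_normalizer` covering `variables` and `chla`
#'   (fitted on `train` when omitted); defines each variable's range.
#' @param grid SOM grid dimensions.
#' @param k Number of fuzzy labels per variable (default 3).
#' @param seed Integer seed.
#' @param resolution Defuzzification grid points over the chla range (default 20001, keeping centroid discretization error well below 0.001 ug/l).
#' @return A `fuzzy_model`.
#' @export
fuzzy_fit <- function(train, variables, spec = NULL, grid = c(6, 6), k = 3,
                      seed = 1L, resolution = 20001) {
  som_vars <- c(variables, "chla")
  train <- limno_series(as.data.frame(train)[, c("index", som_vars)],
                        variables)
  if (is.null(spec)) {
    spec <- fit_normalizer(train, som_vars)
  }
  norm <- apply_normalizer(spec, train)
  som <- train_som(norm, som_vars, grid = grid, seed = seed)
  summaries <- summarize_clusters(som, norm, train, k = k)
  memberships <- lapply(som_vars, function(v) {
    r <- spec$ranges[[v]]
    induce_memberships(summaries, v, c(r["min"], r["max"]))
  })
  names(memberships) <- som_vars
  rules <- induce_rules(train, memberships)
  structure(list(variables = variables, memberships = memberships,
                 rules = rules, spec = spec, som = som,
                 summaries = summaries, resolution = resolution),
            class = "fuzzy_model")
}

#' @export
print.fuzzy_model <- function(x, ...) {
  cons <- vapply(x$rules, function(r) r$consequent, character(1))
  cat(sprintf("<fuzzy_model> %d rules over %s (consequents: %s)\n",
              length(x$rules), paste(x$variables, collapse = ", "),
              paste(names(table(cons)), table(cons), sep = ":",
                    collapse = ", ")))
  invisible(x)
}

#' Export the rulebase as IF-THEN text
#'
#' @param model A `fuzzy_model`.
#' @return Character vector, one human-readable rule per element.
#' @export
format_fuzzy_rules <- function(model) {
  vapply(model$rules, function(r) {
    ante <- paste(sprintf("%s is %s", names(r$antecedent), r$antecedent),
                  collapse = " AND ")
    sprintf("IF %s THEN chla is %s  [support %d]", ante, r$consequent,
            r$support)
  }, character(1))
}

# Mamdani aggregate membership over a chla grid for one sample's label
# activations (named vector label -> firing strength).
aggregate_output <- function(memberships_chla, activations, grid_x) {
  agg <- numeric(length(grid_x))
  for (mf in memberships_chla$functions) {
    act <- activations[[mf$label]]
    if (is.null(act) || act <= 0) next
    agg <- pmax(agg, pmin(membership_eval(mf, grid_x), act))
  }
  agg
}

#' Centre-of-gravity defuzzification
#'
#' Clips each output membership function at its activation, aggregates by
#' max, and returns the centroid `sum(x * mu(x)) / sum(mu(x))` evaluated on
#' a uniform grid of `resolution` points over the output range.
#'
#' @param memberships_chla A `membership_set` for the output variable.
#' @param activations Named numeric vector, label -> firing strength in
#'   \[0, 1\].
#' @param resolution Number of grid points.
#' @return Crisp output value, or range midpoint (with a warning) when the
#'   aggregate has zero area.
#' @export
defuzz_centroid <- function(memberships_chla, activations,
                            resolution = 20001) {
  rng <- memberships_chla$range
  grid_x <- seq(rng[1], rng[2], length.out = resolution)
  agg <- aggregate_output(memberships_chla, activations, grid_x)
  area <- sum(agg)
  if (area <= 0) {
    warning("no rule fired; falling back to output-range midpoint")
    return(mean(rng))
  }
  sum(grid_x * agg) / area
}

#' Predict chlorophyll-a by Mamdani inference
#'
#' Per rule the firing strength is the minimum antecedent membership; per
#' output label the activation is the maximum strength over rules with that
#' consequent; output membership functions are clipped at their activation
#' and aggregated by max; the crisp value is the centre of gravity of the
#' aggregate, integrated numerically on `resolution` points over the
#' chlorophyll-a range. When no rule fires the range midpoint is returned
#' with a warning.
#'
#' @param model A `fuzzy_model`.
#' @param samples Data frame or [limno_series()] with the model variables.
#' @return Numeric vector of predictions, ug/l.
#' @export
fuzzy_predict <- function(model, samples) {
  df <- as.data.frame(samples)
  need <- setdiff(model$variables, names(df))
  if (length(need) > 0) {
    stop("samples lack model variable(s): ", paste(need, collapse = ", "))
  }
  out_labels <- vapply(model$memberships$chla$functions,
                       function(mf) mf$label, character(1))
  vapply(seq_len(nrow(df)), function(i) {
    activations <- stats::setNames(rep(0, length(out_labels)), out_labels)
    for (r in model$rules) {
      strength <- min(vapply(names(r$antecedent), function(v) {
        mfs <- model$memberships[[v]]$functions
        lab <- r$antecedent[[v]]
        mf <- mfs[[which(vapply(mfs, function(m) m$label, character(1)) ==
                           lab)]]
        membership_eval(mf, df[[v]][i])
      }, numeric(1)))
      if (strength > activations[[r$consequent]]) {
        activations[[r$consequent]] <- strength
      }
    }
    defuzz_centroid(model$memberships$chla, activations, model$resolution)
  }, numeric(1))
}
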