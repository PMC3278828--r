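# Shared fixture builders; everything is generated in code, no stored data.

# Tiny deterministic series with all ten variables plus chla.
tiny_series <- function(n = 12, seed = 7) {
  cfg <- synth_config(n = n, seed = seed,
                      mechanism = mechanism_mlr_printed(), noise_sd = 0.5)
  generate_series(cfg)
}

# The published evolved rule, reused across tests.
printed_rule <- function() mechanism_hea_printed()$ruleset

# Mann-Whitney rank statistic with ties counted half: the independent
# oracle for trapezoidal AUC.
auc_rank_oracle <- function(labels, scores) {
  pos <- scores[labels]
  neg <- scores[!labels]
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}

# Brute-force fine-grid centroid of a clipped-max Mamdani aggregate.
centroid_fine_oracle <- function(mset, activations, n_grid = 1e5) {
  gx <- seq(mset$range[1], mset$range[2], length.out = n_grid)
  agg <- rep(0, length(gx))
  for (mf in mset$functions) {
    a <- activations[[mf$label]]
    if (!is.null(a) && a > 0) {
      agg <- pmax(agg, pmin(membership_eval(mf, gx), a))
    }
  }
  sum(gx * agg) / sum(agg)
}

# TRUE iff a rule set passes the boolean/arithmetic typing validator.
validate_rule_ok <- function(r) {
  isTRUE(tryCatch(limnocast:::validate_rule(r), error = function(e) FALSE))
}

# Flatten / restore network weights, for finite-difference checks.
rann_flatten <- function(m) unlist(m[c("W_ih", "W_ch", "W_ho", "b_h", "b_o")])
rann_unflatten <- function(m, v) {
  i <- 0
  for (nm in c("W_ih", "W_ch", "W_ho", "b_h", "b_o")) {
    k <- length(m[[nm]])
    m[[nm]][] <- v[i + seq_len(k)]
    i <- i + k
  }
  m
}
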