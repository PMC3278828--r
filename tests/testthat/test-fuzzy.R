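test_that("SOM finds best-matching units and is seed-deterministic", {
  s <- tiny_series(40, seed = 3)
  spec <- fit_normalizer(s)
  norm <- apply_normalizer(spec, s)
  g1 <- train_som(norm, c("DO", "pH", "chla"), grid = c(2, 2), seed = 5)
  g2 <- train_som(norm, c("DO", "pH", "chla"), grid = c(2, 2), seed = 5)
  expect_identical(g1$prototypes, g2$prototypes)
  # a sample equal to a prototype maps to that node
  proto_sample <- as.data.frame(t(g1$prototypes[3, ]))
  expect_identical(som_bmu(g1, proto_sample), 3L)
  expect_error(train_som(norm[1:3, ], c("DO", "pH"), grid = c(2, 2)),
               "fewer samples")
})

test_that("a 1x2 map separates two well-separated blobs", {
  set.seed(10)
  blob <- data.frame(
    DO = c(rnorm(30, 0.2, 0.02), rnorm(30, 0.8, 0.02)),
    chla = c(rnorm(30, 0.25, 0.02), rnorm(30, 0.75, 0.02)))
  g <- train_som(blob, c("DO", "chla"), grid = c(1, 2), seed = 2)
  centers <- sort(g$prototypes[, "DO"])
  expect_lt(abs(centers[1] - 0.2), 0.08)
  expect_lt(abs(centers[2] - 0.8), 0.08)
})

test_that("cluster summaries carry t-based 97.5% bands", {
  set.seed(4)
  # two tight, separated clusters in one dimension
  x <- c(rnorm(40, 0.2, 0.01), rnorm(40, 0.8, 0.01))
  df <- data.frame(DO = x, chla = x)
  g <- train_som(df, c("DO", "chla"), grid = c(1, 2), seed = 1)
  cs <- summarize_clusters(g, df, df, k = 2)
  expect_equal(sum(vapply(cs$clusters, `[[`, numeric(1), "count")), 80)
  for (cl in cs$clusters) {
    row <- cl$stats[cl$stats$variable == "DO", ]
    expect_lte(row$lower, row$mean)
    expect_gte(row$upper, row$mean)
    # t-interval oracle on the member samples
    members <- df$DO[som_bmu(g, df) %in%
                       which(stats::cutree(hclust(dist(g$prototypes),
                                                  "ward.D2"), 2) == cl$id)]
    half <- qt(1 - 0.025 / 2, length(members) - 1) *
      sd(members) / sqrt(length(members))
    expect_equal(row$upper - row$mean, half, tolerance = 1e-10)
  }
  expect_false(any(cs$overlap$overlap))  # separated blobs: no overlap

  # zero-variance cluster degenerates to a point interval
  const <- data.frame(DO = rep(c(0.2, 0.8), each = 10),
                      chla = rep(c(0.2, 0.8), each = 10))
  gc <- train_som(const, c("DO", "chla"), grid = c(1, 2), seed = 1,
                  epochs = 200)
  csc <- summarize_clusters(gc, const, const, k = 2)
  row <- csc$clusters[[1]]$stats[1, ]
  expect_equal(row$lower, row$mean)
  expect_equal(row$upper, row$mean)
})

test_that("triangular memberships anchor peaks at cluster means", {
  mset <- induce_memberships(c(2, 5, 8), "DO", c(0, 10))
  med <- mset$functions[[2]]
  expect_identical(med$label, "medium")
  expect_equal(med$peak, 5)
  expect_equal(c(med$left, med$right), c(2, 8))
  expect_equal(membership_eval(med, 5), 1.0)
  # halfway between adjacent peaks both memberships are 0.5
  expect_equal(membership_eval(mset$functions[[1]], 3.5), 0.5)
  expect_equal(membership_eval(med, 3.5), 0.5)
  # shoulders: full membership out to the range ends
  expect_equal(membership_eval(mset$functions[[1]], c(0, 1, 2)), c(1, 1, 1))
  expect_equal(membership_eval(mset$functions[[3]], c(8, 9, 10)), c(1, 1, 1))
  # adjacent labels sum to 1 between peaks; all degrees within [0, 1]
  xs <- seq(0, 10, by = 0.1)
  for (fn in mset$functions) {
    expect_true(all(membership_eval(fn, xs) >= 0 &
                      membership_eval(fn, xs) <= 1))
  }
  mid <- seq(2, 8, by = 0.1)
  sums <- membership_eval(mset$functions[[1]], mid) +
    membership_eval(mset$functions[[2]], mid) +
    membership_eval(mset$functions[[3]], mid)
  expect_equal(sums, rep(1, length(mid)), tolerance = 1e-12)
  expect_error(induce_memberships(c(2, 2, 8), "DO", c(0, 10)),
               "degenerate")
})

test_that("case-based rule induction aggregates and resolves conflicts", {
  mems <- list(
    DO = induce_memberships(c(2, 5, 8), "DO", c(0, 10)),
    chla = induce_memberships(c(1, 5, 9), "chla", c(0, 10)))
  one <- induce_rules(data.frame(DO = 2.6, chla = 1),
                                          mems)
  expect_identical(length(one), 1L)
  expect_identical(one[[1]]$consequent, "low")

  two_same <- induce_rules(
    data.frame(DO = c(2.6, 2.6), chla = c(1, 1)), mems)
  expect_identical(length(two_same), 1L)
  expect_identical(two_same[[1]]$support, 2L)

  # conflicting consequents: degrees 0.8*1.0 (low) vs 0.6*1.0 (high)
  conflict <- induce_rules(
    data.frame(DO = c(2.6, 3.2), chla = c(1, 9)), mems)
  expect_identical(length(conflict), 1L)
  expect_identical(conflict[[1]]$consequent, "low")
  expect_equal(conflict[[1]]$degree, 0.8, tolerance = 1e-12)
  expect_identical(conflict[[1]]$support, 1L)
})

test_that("centroid defuzzification matches symmetry and the fine-grid
           oracle", {
  mset <- induce_memberships(c(8, 16, 24), "chla", c(0, 32))
  # fully activated symmetric middle triangle: centroid at its peak
  expect_equal(defuzz_centroid(mset, c(low = 0, medium = 1, high = 0)), 16,
               tolerance = 1e-9)
  # clipping a symmetric triangle keeps the centroid at the peak
  expect_equal(defuzz_centroid(mset, c(low = 0, medium = 0.5, high = 0)),
               16, tolerance = 1e-9)
  set.seed(77)
  for (i in 1:50) {
    means <- sort(runif(3, 2, 30))
    if (min(diff(means)) < 0.5) next
    ms <- induce_memberships(means, "chla", c(0, 31.7))
    act <- setNames(runif(3), c("low", "medium", "high"))
    got <- defuzz_centroid(ms, act)
    expect_equal(got, centroid_fine_oracle(ms, act), tolerance = 1e-3)
    expect_gte(got, 0)
    expect_lte(got, 31.7)
  }
  expect_warning(out <- defuzz_centroid(mset, c(low = 0, medium = 0,
                                                high = 0)),
                 "no rule fired")
  expect_equal(out, 16)
})

test_that("the fitted fuzzy model fires on every training case and behaves
           monotonely on a one-variable fixture", {
  s <- generate_series(synth_config(n = 60, seed = 13, noise_sd = 1))
  model <- fuzzy_fit(s, c("DO", "pH"), grid = c(3, 3), seed = 2)
  expect_gte(length(model$rules), 1L)
  expect_no_warning(preds <- fuzzy_predict(model, s))
  rng <- model$memberships$chla$range
  expect_true(all(preds >= rng[1] & preds <= rng[2]))
  txt <- format_fuzzy_rules(model)
  expect_match(txt[1], "^IF .* THEN chla is")

  # hand-built single-input model: low DO -> low chla, high DO -> high chla
  mems <- list(DO = induce_memberships(c(6, 7.5, 9), "DO", c(5, 10)),
               chla = induce_memberships(c(4, 10, 20), "chla", c(0, 30)))
  rules <- list(
    list(antecedent = c(DO = "low"), consequent = "low", support = 1L),
    list(antecedent = c(DO = "medium"), consequent = "medium", support = 1L),
    list(antecedent = c(DO = "high"), consequent = "high", support = 1L))
  mono <- structure(list(variables = "DO", memberships = mems,
                         rules = rules, resolution = 2001),
                    class = "fuzzy_model")
  xs <- data.frame(DO = seq(5, 10, by = 0.25))
  out <- fuzzy_predict(mono, xs)
  expect_false(is.unsorted(out))
})
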