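test_that("initialization is seeded, bounded and correctly shaped", {
  cfg <- rann_config(n_inputs = 6, seed = 99)
  m1 <- rann_init(cfg)
  m2 <- rann_init(cfg)
  expect_identical(rann_flatten(m1), rann_flatten(m2))
  expect_identical(m1$context, rep(0, 4))
  w <- rann_flatten(m1)
  expect_true(all(abs(w) <= 0.5))
  # 6-4-1 with context and biases: 6*4 + 4*4 + 4*1 + 4 + 1 = 49 weights
  expect_identical(length(w), 49L)
  expect_true(all(vapply(m1$prev_delta, function(d) all(d == 0),
                         logical(1))))
})

test_that("forward pass applies tanh(alpha x) and carries context", {
  cfg <- rann_config(n_inputs = 1, n_hidden = 1, slope_alpha = 0.7)
  m <- rann_init(cfg)
  m$W_ih[] <- 1; m$W_ch[] <- 0; m$W_ho[] <- 1; m$b_h[] <- 0; m$b_o[] <- 0
  st <- limnocast:::rann_forward_states(m, matrix(1), h0 = 0)
  expect_equal(st$H[1, 1], tanh(0.7), tolerance = 1e-12)  # 0.604368
  expect_equal(st$Y[1], tanh(0.7 * tanh(0.7)), tolerance = 1e-12)

  zero <- rann_init(rann_config(n_inputs = 3, seed = 1))
  for (nm in c("W_ih", "W_ch", "W_ho", "b_h", "b_o")) zero[[nm]][] <- 0
  X <- matrix(runif(12), 4, 3)
  expect_equal(rann_forward(zero, X), rep(0, 4))

  # resetting the context makes repeated runs identical; outputs bounded
  m2 <- rann_init(rann_config(n_inputs = 3, seed = 5))
  y1 <- rann_forward(m2, X, reset = TRUE)
  y2 <- rann_forward(m2, X, reset = TRUE)
  expect_identical(y1, y2)
  expect_true(all(abs(y1) < 1))

  # with the recurrent weights zeroed the net is a plain one-hidden-layer
  # feed-forward map: permuting time steps permutes outputs
  m2$W_ch[] <- 0
  y <- rann_forward(m2, X)
  expect_equal(rann_forward(m2, X[4:1, , drop = FALSE]), y[4:1],
               tolerance = 1e-12)
  expect_error(rann_forward(m2, X[, 1:2]), "expects")
})

test_that("BPTT gradients match central finite differences on a 3-2-1
           net", {
  worst <- 0
  for (trial in 1:20) {
    cfg <- rann_config(n_inputs = 3, n_hidden = 2, seed = trial)
    m <- rann_init(cfg)
    set.seed(1000 + trial)
    X <- matrix(runif(15), 5, 3)
    tg <- runif(5)
    h0 <- rep(0, 2)
    g <- unlist(limnocast:::rann_bptt_gradients(m, X, tg, h0)$grads)
    loss <- function(v) {
      mm <- rann_unflatten(m, v)
      y <- limnocast:::rann_forward_states(mm, X, h0)$Y
      0.5 * sum((y - tg)^2)
    }
    v0 <- rann_flatten(m)
    h <- 1e-5
    fd <- vapply(seq_along(v0), function(k) {
      vp <- v0; vp[k] <- vp[k] + h
      vm <- v0; vm[k] <- vm[k] - h
      (loss(vp) - loss(vm)) / (2 * h)
    }, numeric(1))
    rel <- abs(g - fd) / pmax(abs(fd), 1e-6)
    worst <- max(worst, max(rel))
  }
  expect_lt(worst, 1e-4)
})

test_that("the momentum rule reproduces the worked weight update", {
  cfg <- rann_config(n_inputs = 1, n_hidden = 1, learning_rate = 0.01,
                     momentum = 0.9)
  m <- rann_init(cfg)
  m$W_ih[] <- 0.5
  m$prev_delta$W_ih[] <- 0.1  # w(n) - w(n-1) = 0.5 - 0.4
  # eta*delta*x = 0.01 * 2 * 1, so the loss gradient is -delta*x = -2
  grads <- list(W_ih = matrix(-2))
  m2 <- limnocast:::rann_apply_update(m, grads)
  expect_equal(m2$W_ih[1, 1], 0.5 + 0.02 + 0.09, tolerance = 1e-12)
  # zero momentum reduces to the plain gradient step
  m$config$momentum <- 0
  m3 <- limnocast:::rann_apply_update(m, grads)
  expect_equal(m3$W_ih[1, 1], 0.52, tolerance = 1e-12)
})

test_that("training improves fit and returns the best-validation weights", {
  s <- generate_series(synth_config(n = 150, seed = 41,
                                    mechanism = mechanism_mlr_printed(),
                                    noise_sd = 0.5))
  sp <- split_series(s, c(0.6, 0.2, 0.2))
  spec <- fit_normalizer(sp$train_A)
  nA <- apply_normalizer(spec, sp$train_A)
  nC <- apply_normalizer(spec, sp$validate_C)
  cfg <- rann_config(6, seed = 3, max_epochs = 150, patience = 150,
                     epoch_size = 10)
  vars <- c("WaterTemp", "pH", "DO", "Secchi", "NH3N", "NO3N")
  m <- rann_init(cfg, vars)
  trained <- rann_train(m, nA, nC, cfg)
  h <- attr(trained, "history")
  expect_false(is.unsorted(rev(cummin(h$train_rmse))))
  # returned weights achieve the minimum validation RMSE seen
  val_pred <- rann_forward(trained, nC)
  expect_equal(sqrt(mean((val_pred - nC$chla)^2)), min(h$val_rmse),
               tolerance = 1e-10)
  expect_lt(min(h$train_rmse), h$train_rmse[1])

  preds <- rann_predict(trained, sp$test_B, spec)
  expect_identical(length(preds), nrow(sp$test_B))
  expect_error(rann_train(m, nA, nC[0, ], cfg), "validation")
})

test_that("inverse normalization maps network outputs back to ug/l", {
  spec <- structure(list(ranges = list(chla = c(min = 0, max = 31.70))),
                    class = "limno_normalizer")
  expect_equal(normalize_values(spec, "chla", 0.5, "inverse"), 15.85)
  expect_equal(normalize_values(spec, "chla", 0, "inverse"), 0)
})

test_that("sensitivity analysis ranks the load-bearing input first", {
  cfg <- rann_config(n_inputs = 2, seed = 6)
  m <- rann_init(cfg, c("DO", "TSS"))
  m$W_ih[, 2] <- 0  # second input disconnected
  s <- tiny_series(25, seed = 14)
  spec <- fit_normalizer(s)
  norm <- apply_normalizer(spec, s)
  rep <- sensitivity_analysis(m, norm)
  expect_identical(rep$variable[1], "DO")
  expect_equal(rep$sensitivity[rep$variable == "TSS"], 0)
  expect_false(is.unsorted(rev(rep$sensitivity)))

  zero <- m
  for (nm in c("W_ih", "W_ch", "W_ho", "b_h", "b_o")) zero[[nm]][] <- 0
  expect_warning(rep0 <- sensitivity_analysis(zero, norm), "untrained")
  expect_true(all(rep0$sensitivity == 0))
})

test_that("backward elimination discards a pure-noise input", {
  s <- generate_series(synth_config(n = 160, seed = 19,
                                    mechanism = mechanism_mlr_printed(),
                                    noise_sd = 0.3))
  sp <- split_series(s, c(0.6, 0.2, 0.2))
  spec <- fit_normalizer(sp$train_A)
  norm_split <- structure(list(
    train_A = apply_normalizer(spec, sp$train_A),
    test_B = apply_normalizer(spec, sp$test_B),
    validate_C = apply_normalizer(spec, sp$validate_C)),
    class = "limno_split")
  cfg <- rann_config(2, seed = 8, max_epochs = 120, patience = 120,
                     epoch_size = 10)
  res <- backward_eliminate(norm_split, c("DO", "Conductivity"), cfg)
  expect_identical(res$selected, "DO")
  res2 <- backward_eliminate(norm_split, c("DO", "Conductivity"), cfg)
  expect_identical(res2$trace, res$trace)  # seed-reproducible
  one <- backward_eliminate(norm_split, "DO", cfg)
  expect_identical(one$selected, "DO")
})
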