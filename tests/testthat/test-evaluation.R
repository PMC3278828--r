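test_that("rmse matches its closed form", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(25 / 2), tolerance = 1e-12)
  expect_equal(rmse(5, 2), 3)  # single pair reduces to |y - yhat|
  # translation of a perfect fit by c gives rmse |c|
  y <- rnorm(20)
  expect_equal(rmse(y, y + 1.7), 1.7, tolerance = 1e-12)
  expect_error(rmse(numeric(0), numeric(0)), "non-empty")
  expect_error(rmse(1:3, 1:2), "equal length")
})

test_that("pearson_r flags reliability at 0.5 and rejects constants", {
  y <- c(1, 3, 2, 5, 4)
  expect_equal(as.numeric(pearson_r(y, 2 * y + 1)), 1)
  expect_equal(as.numeric(pearson_r(y, -y)), -1)
  expect_true(attr(pearson_r(y, 2 * y + 1), "reliable"))
  expect_error(pearson_r(y, rep(1, 5)), "constant")
  # invariant under positive affine transforms of either argument
  x <- rnorm(30)
  z <- x + rnorm(30)
  expect_equal(as.numeric(pearson_r(x, z)),
               as.numeric(pearson_r(3 * x + 2, 0.5 * z - 1)),
               tolerance = 1e-12)
})

test_that("trapezoidal AUC equals the rank-statistic oracle, with ties", {
  set.seed(31)
  for (i in 1:100) {
    n <- sample(4:50, 1)
    chla <- runif(n, 0, 30)
    if (all(chla >= 8) || all(chla < 8)) next
    # round some scores so ties occur
    scores <- round(runif(n, 0, 30), sample(0:2, 1))
    roc <- roc_auc(chla, scores, 8)
    expect_equal(roc$auc, auc_rank_oracle(chla >= 8, scores),
                 tolerance = 1e-12)
  }
})

test_that("ROC curve geometry: endpoints, monotonicity, vertex count", {
  chla <- c(10, 12, 3, 4, 9, 1)
  scores <- c(8.1, 9.2, 2.0, 3.3, 7.7, 0.4)  # perfect ranking, tie-free
  roc <- roc_auc(chla, scores, 8)
  expect_equal(roc$auc, 1)
  expect_equal(unlist(roc$points[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(roc$points[nrow(roc$points), ]), c(fpr = 1, tpr = 1))
  expect_false(is.unsorted(roc$points$fpr))
  expect_false(is.unsorted(roc$points$tpr))
  expect_identical(nrow(roc$points), length(unique(scores)) + 1L)

  # perfectly inverted scores give AUC 0
  expect_equal(roc_auc(c(10, 3), c(0.2, 0.9), 8)$auc, 0)

  # complementing the scores complements the area (tie-free)
  set.seed(8)
  chla <- runif(30, 0, 30)
  sc <- rnorm(30)
  expect_equal(roc_auc(chla, sc, 8)$auc + roc_auc(chla, -sc, 8)$auc, 1,
               tolerance = 1e-12)

  expect_error(roc_auc(c(10, 12), c(1, 2), 8), "degenerate")
})

test_that("AUC grading uses the 0.7/0.8/0.9 cuts", {
  expect_identical(grade_auc(0.84), "excellent")
  expect_identical(grade_auc(0.76), "acceptable")
  expect_identical(grade_auc(0.95), "outstanding")
  expect_identical(grade_auc(0.9), "excellent")
  expect_identical(grade_auc(0.65), "poor")
  expect_error(grade_auc(1.2), "\\[0, 1\\]")
})

test_that("evaluate_model assembles the three criteria and survives a
           constant predictor", {
  s <- tiny_series(30, seed = 2)
  perfect <- evaluate_model(function(x) x$chla, s, boundary = 8,
                            model_name = "oracle")
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$auc, 1)
  expect_identical(perfect$n, 30L)

  expect_warning(
    flat <- evaluate_model(function(x) rep(5, nrow(x)), s, 8, "flat"),
    "undefined")
  expect_true(is.finite(flat$rmse))
  expect_true(is.na(flat$r))

  two <- rbind(perfect, flat)
  expect_identical(two$model, c("oracle", "flat"))
})
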