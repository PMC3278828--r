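test_that("CSV round trip preserves a series and drops incomplete rows", {
  s <- tiny_series(5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_series_csv(s, path)
  expect_identical(length(readLines(path)), 6L)  # header + 5 rows
  back <- read_series_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(s), tolerance = 1e-12)

  # a hole in DO drops exactly that row, with a message
  df <- as.data.frame(s)
  df$DO[2] <- NA
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path2, row.names = FALSE)
  expect_message(back2 <- read_series_csv(path2), "1 row")
  expect_identical(nrow(back2), 4L)
  expect_false(2 %in% back2$index)

  expect_error(write_series_csv(s[0, ], path), "empty")
  expect_error(read_series_csv(withr::local_tempfile()), "not found")
})

test_that("normalization maps the training range onto [0,1] and inverts", {
  s <- tiny_series(20)
  spec <- fit_normalizer(s)
  # fitted ranges bracket every training value
  for (v in c(limno_variables(), "chla")) {
    expect_lte(spec$ranges[[v]]["min"], min(s[[v]]))
    expect_gte(spec$ranges[[v]]["max"], max(s[[v]]))
  }
  fwd <- apply_normalizer(spec, s)
  for (v in limno_variables()) {
    expect_true(all(fwd[[v]] >= 0 & fwd[[v]] <= 1))
  }
  back <- apply_normalizer(spec, fwd, direction = "inverse")
  expect_equal(as.data.frame(back), as.data.frame(s), tolerance = 1e-12)

  # the Secchi range of the summary table maps its end points to 0 and 1
  spec$ranges$Secchi <- c(min = 0.30, max = 1.75)
  expect_equal(normalize_values(spec, "Secchi", c(0.30, 1.75)), c(0, 1))

  const <- s
  const$pH <- 5
  expect_error(fit_normalizer(const), "pH")
  expect_message(
    apply_normalizer(spec, transform(as.data.frame(s), Secchi = 2)[1, ] |>
                       limno_series()),
    "outside the training range")
})

test_that("series splitting partitions samples deterministically", {
  s <- tiny_series(10)
  sp <- split_series(s, c(0.6, 0.2, 0.2), "contiguous")
  expect_identical(c(nrow(sp$train_A), nrow(sp$test_B), nrow(sp$validate_C)),
                   c(6L, 2L, 2L))
  expect_identical(sort(c(sp$train_A$index, sp$test_B$index,
                          sp$validate_C$index)), s$index)
  # contiguous mode preserves time order in blocks
  expect_identical(sp$train_A$index, 1:6)
  expect_identical(sp$test_B$index, 7:8)

  all_a <- split_series(s, c(1, 0, 0))
  expect_identical(nrow(all_a$train_A), 10L)
  expect_identical(nrow(all_a$test_B), 0L)

  i1 <- split_series(s, c(0.6, 0.2, 0.2), "interleaved", seed = 4)
  i2 <- split_series(s, c(0.6, 0.2, 0.2), "interleaved", seed = 4)
  expect_identical(i1$train_A$index, i2$train_A$index)
  expect_identical(sort(c(i1$train_A$index, i1$test_B$index,
                          i1$validate_C$index)), s$index)
  # indices stay ordered within each interleaved set
  expect_false(is.unsorted(i1$train_A$index))

  expect_error(split_series(s[1:2, ], c(0.4, 0.3, 0.3)), "small")
})

test_that("trophic classification respects the printed boundary directions", {
  expect_identical(classify_trophic(0.5), "ultra-oligotrophic")
  expect_identical(classify_trophic(1.0), "ultra-oligotrophic")
  expect_identical(classify_trophic(2.5), "oligotrophic")
  expect_identical(classify_trophic(8.0), "mesotrophic")
  expect_identical(classify_trophic(24.999), "eutrophic")
  expect_identical(classify_trophic(25.0), "hypertrophic")
  expect_identical(classify_trophic(30.0), "hypertrophic")
  expect_error(classify_trophic(-1), "non-negative")
  # monotone in chla
  x <- sort(runif(200, 0, 40))
  states <- classify_trophic(x)
  ranks <- match(states, trophic_scale()$labels)
  expect_false(is.unsorted(ranks))
})
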