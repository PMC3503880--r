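test_that("compiled CV inner loop equals the pure-R reference oracle", {
  fx <- make_null_features(seed = 1, n = 24, T = 12, P = 3)
  fx$values[fx$conditions == "left", 4:6, ] <-
    fx$values[fx$conditions == "left", 4:6, ] + 1   # some structure
  res <- crossval_accuracy(fx, fx$conditions, k = 4, seed = 2)
  ref <- ref_cv_accuracy(fx, fx$conditions, res$folds)
  expect_equal(res$raw, ref, tolerance = 1e-12)
})

test_that("cross-validation tests each trial exactly once", {
  fx <- make_null_features(seed = 3, n = 70)
  res <- crossval_accuracy(fx, fx$conditions, k = 10, seed = 4)
  expect_length(res$folds, 70)
  expect_equal(sort(unique(res$folds)), 1:10)
  expect_true(all(tabulate(res$folds, 10) %in% 6:8))
  # stratification: both classes in every fold
  for (f in 1:10) {
    expect_length(unique(fx$conditions[res$folds == f]), 2)
  }
})

test_that("smoothing: constant unchanged, bounded by raw extremes, max not raised", {
  expect_equal(smooth_timecourse(rep(0.7, 50)), rep(0.7, 50))
  x <- with_seed(5, runif(100))
  s <- smooth_timecourse(x)
  expect_lte(max(s), max(x))
  expect_gte(min(s), min(x))
})

test_that("separability confined to time-points 40-60 localizes accuracy there", {
  fx <- make_null_features(seed = 6, n = 40)
  act <- fx$conditions == "left"
  fx$values[act, 40:60, ] <- fx$values[act, 40:60, ] + 10
  res <- crossval_accuracy(fx, fx$conditions, k = 10, seed = 7)
  expect_gt(min(res$raw[45:55]), 0.95)
  expect_lt(mean(res$raw[c(1:30, 70:100)]), 0.65)
})

test_that("null features keep smoothed accuracy near chance (spot check)", {
  ok <- vapply(1:10, function(s) {
    fx <- make_null_features(seed = 100 + s)
    res <- crossval_accuracy(fx, fx$conditions, k = 10, seed = 200 + s)
    all(res$smoothed >= 0.35 & res$smoothed <= 0.65)
  }, TRUE)
  expect_gte(mean(ok), 0.9)
})

test_that("results are fully deterministic given data and seed", {
  fx <- make_null_features(seed = 8)
  a <- crossval_accuracy(fx, fx$conditions, k = 10, seed = 9)
  b <- crossval_accuracy(fx, fx$conditions, k = 10, seed = 9)
  expect_identical(a$raw, b$raw)
  expect_identical(a$folds, b$folds)
  f1 <- familywise_permutation_test(fx, fx$conditions, n_perm = 100, seed = 9)
  f2 <- familywise_permutation_test(fx, fx$conditions, n_perm = 100, seed = 9)
  expect_identical(f1$null, f2$null)
  expect_identical(f1$p, f2$p)
})
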