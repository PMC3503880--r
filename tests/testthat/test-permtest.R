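test_that("constant features stay at chance with no significant time-points", {
  fx <- make_null_features(seed = 1, n = 30, T = 20)
  fx$values[] <- 1
  expect_warning(
    res <- familywise_permutation_test(fx, fx$conditions, n_perm = 50,
                                       seed = 2),
    "unstable")
  # ties -> rest: every prediction is "rest", so accuracy sits at the
  # rest fraction (0.5 here) at every time-point
  expect_length(unique(res$observed$raw), 1)
  expect_equal(res$observed$raw[1], 0.5)
  expect_false(any(res$significant))
  expect_true(all(res$p == 1))
})

test_that("band restriction: full set is the identity, subsets shrink features", {
  fx <- make_null_features(seed = 3, n = 30, T = 20)
  full <- band_restricted_classification(fx, fx$conditions,
                                         names(smr_bands),
                                         n_perm = 100, seed = 4)
  direct <- crossval_accuracy(fx, fx$conditions, seed = 4)
  expect_identical(full$accuracy$raw, direct$raw)

  hb <- subset_bands(fx, "high_beta")
  expect_equal(dim(hb$values)[3], 2)
  expect_equal(dimnames(hb$values)[[3]], c("C3'_high_beta", "C4'_high_beta"))
  expect_error(subset_bands(fx, character(0)))
  expect_error(subset_bands(fx, "gamma"))
})

test_that("high-beta-only classification beats all-band at the effect peak when the ERS is confined there", {
  # noise-dilution: effect lives only in 25-30 Hz, so dropping the other
  # six (noise) features should help at the effect's peak time
  wins <- vapply(1:12, function(s) {
    ep <- simulate_responder_epochs(seed = 700 + s, depth = 1, n_blocks = 2,
                                    match_counts = NULL)
    idx <- which(ep$conditions %in% c("left", "rest"))
    fx <- subset_feature_trials(extract_bandpower(ep), idx)
    labs <- ep$conditions[idx]
    all4 <- crossval_accuracy(fx, labs, seed = s)
    hb <- crossval_accuracy(subset_bands(fx, "high_beta"), labs, seed = s)
    peak <- which.max(hb$smoothed)
    hb$smoothed[peak] >= all4$smoothed[peak]
  }, TRUE)
  expect_gte(mean(wins), 0.6)
})

test_that("familywise p-values fall as the simulated ERS deepens", {
  # scaled down from the stated 25-seed x 4-depth sweep (2 blocks,
  # n_perm = 100) to stay inside the suite's runtime budget
  depths <- c(0, 0.25, 0.5, 1.0)
  med_p <- vapply(depths, function(dep) {
    pmin <- vapply(1:10, function(s) {
      ep <- simulate_responder_epochs(seed = 900 + s, depth = dep,
                                      n_blocks = 2, match_counts = NULL)
      idx <- which(ep$conditions %in% c("left", "rest"))
      fx <- subset_feature_trials(extract_bandpower(ep), idx)
      fw <- familywise_permutation_test(fx, ep$conditions[idx],
                                        n_perm = 100, seed = 50 + s)
      min(fw$p)
    }, 0)
    median(pmin)
  }, 0)
  expect_lt(med_p[4], med_p[1])
  expect_lte(med_p[4], med_p[2])
  expect_lte(med_p[3], med_p[1])
})
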