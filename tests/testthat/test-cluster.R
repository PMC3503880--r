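test_that("4-adjacency: shared edges cluster, diagonal/gap cells do not", {
  mask <- matrix(FALSE, 25, 10)
  mask[10, 4] <- mask[11, 4] <- mask[20, 4] <- TRUE   # 10 & 11 Hz adjacent
  comps <- smrdetect:::grid_components(mask)
  expect_length(comps, 2)
  sizes <- sort(vapply(comps, length, 0L))
  expect_equal(sizes, c(1L, 2L))

  mask2 <- matrix(FALSE, 5, 5)
  mask2[2, 2] <- mask2[3, 3] <- TRUE                  # diagonal only
  expect_length(smrdetect:::grid_components(mask2), 2)
})

test_that("a strong localized mean shift is recovered as a significant cluster", {
  n1 <- 20; n2 <- 20; nf <- 15; nt <- 30
  A <- with_seed(1, array(rnorm(n1 * nf * nt), c(n1, nf, nt)))
  B <- with_seed(2, array(rnorm(n2 * nf * nt), c(n2, nf, nt)))
  A[, 5:7, 10:15] <- A[, 5:7, 10:15] + 2
  res <- cluster_permutation_test(A, B, n_perm = 200, seed = 3)
  df <- summary(res)
  sig <- df[df$significant & df$sign == "+", , drop = FALSE]
  expect_gte(nrow(sig), 1)
  expect_lte(sig$f_min[1], 5)
  expect_gte(sig$f_max[1], 7)
})

test_that("label swap flips cluster signs; p-values agree to MC precision", {
  # observed statistics are exactly antisymmetric under operand swap;
  # the Monte Carlo null is redrawn (different random partitions of the
  # row-swapped data), so p-values agree in distribution, to within
  # binomial noise of the n_perm = 400 null
  n <- 18; nf <- 10; nt <- 20
  A <- with_seed(4, array(rnorm(n * nf * nt), c(n, nf, nt)))
  B <- with_seed(5, array(rnorm(n * nf * nt), c(n, nf, nt)))
  A[, 3:4, 5:9] <- A[, 3:4, 5:9] + 1.5
  r1 <- summary(cluster_permutation_test(A, B, n_perm = 400, seed = 6))
  r2 <- summary(cluster_permutation_test(B, A, n_perm = 400, seed = 6))
  r1 <- r1[order(r1$f_min, r1$t_min, r1$sign), ]
  r2 <- r2[order(r2$f_min, r2$t_min, r2$sign), ]
  expect_equal(nrow(r1), nrow(r2))
  expect_equal(r1$stat, -r2$stat)
  expect_equal(r1$f_min, r2$f_min)
  expect_equal(r1$t_min, r2$t_min)
  expect_equal(r1$sign, chartr("+-", "-+", r2$sign))
  expect_lt(max(abs(r1$p - r2$p)), 0.12)   # > 3 SD of the p difference
})

test_that("zero-variance cells are excluded with a warning", {
  n <- 10; nf <- 4; nt <- 6
  A <- with_seed(7, array(rnorm(n * nf * nt), c(n, nf, nt)))
  B <- with_seed(8, array(rnorm(n * nf * nt), c(n, nf, nt)))
  A[, 2, 3] <- 1; B[, 2, 3] <- 1
  expect_warning(res <- cluster_permutation_test(A, B, n_perm = 50, seed = 9),
                 "zero variance")
  expect_length(res$channels[[1]]$excluded_cells, 1)
})

test_that("permutation p-values carry the +1 correction (never zero)", {
  n <- 12; nf <- 6; nt <- 8
  A <- with_seed(10, array(rnorm(n * nf * nt), c(n, nf, nt))) + 5
  B <- with_seed(11, array(rnorm(n * nf * nt), c(n, nf, nt)))
  df <- summary(cluster_permutation_test(A, B, n_perm = 100, seed = 12))
  expect_true(all(df$p >= 1 / 101))
  expect_true(all(df$p <= 1))
})
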