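test_that("separable classes are recovered exactly", {
  x <- rbind(matrix(0 + 1e-6 * (1:20), 10, 2),
             matrix(1 + 1e-6 * (1:20), 10, 2))
  labels <- rep(c("rest", "left"), each = 10)
  m <- nb_fit(x, labels)
  expect_equal(unname(m$means["rest", ]), colMeans(x[1:10, ]))
  expect_equal(unname(m$means["left", ]), colMeans(x[11:20, ]))
  pred <- nb_predict(m, x)
  expect_equal(pred$class, labels)
})

test_that("identical class distributions give posterior ~ prior", {
  x <- matrix(rep(c(1, 2), 12), 12, 2, byrow = TRUE)
  labels <- rep(c("rest", "left"), c(8, 4))
  m <- nb_fit(x, labels)
  p <- nb_predict(m, c(1, 2))
  expect_equal(unname(p$posterior["rest"]), 8 / 12, tolerance = 1e-9)
  expect_equal(p$class, "rest")
})

test_that("posterior matches the closed-form two-Gaussian Bayes rule", {
  for (seed in 1:25) {
    dat <- with_seed(seed, {
      n0 <- sample(3:6, 1); n1 <- sample(3:6, 1)
      list(x = c(rnorm(n0, 0, 1), rnorm(n1, 1.5, 2)),
           labels = rep(c("rest", "left"), c(n0, n1)),
           test = rnorm(8, 0.5, 2))
    })
    m <- nb_fit(matrix(dat$x, ncol = 1), dat$labels)
    i0 <- dat$labels == "rest"
    for (xt in dat$test) {
      p_left <- closed_form_posterior(
        xt,
        mean(dat$x[i0]), max(sd(dat$x[i0]), 1e-12),
        mean(dat$x[!i0]), max(sd(dat$x[!i0]), 1e-12),
        mean(i0), mean(!i0))
      got <- nb_predict(m, xt)
      expect_equal(unname(got$posterior["left"]), p_left, tolerance = 1e-10)
      expect_equal(got$class, if (p_left > 0.5) "left" else "rest")
    }
  }
})

test_that("exact midpoint with equal priors/SDs ties toward rest", {
  x <- matrix(c(rnorm(6, 0, 1e-8), 1 + rnorm(6, 0, 1e-8)), ncol = 1)
  labels <- rep(c("rest", "left"), each = 6)
  m <- nb_fit(x, labels)
  m$means[] <- c(0, 1)      # idealize: exact symmetric means/SDs
  m$sds[] <- 0.3
  m$log_priors[] <- log(0.5)
  p <- nb_predict(m, 0.5)
  expect_equal(unname(p$posterior), c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(p$class, "rest")
})

test_that("a lopsided prior decides an equidistant point", {
  x <- matrix(c(rnorm(9, 0, 1e-6), rnorm(3, 1, 1e-6) ), ncol = 1)
  labels <- rep(c("left", "rest"), c(9, 3))
  m <- nb_fit(x, labels)
  m$means[] <- c(0, 1); m$sds[] <- 1
  expect_equal(nb_predict(m, 0.5)$class, "left")   # prior 0.75 wins
})

test_that("degenerate inputs error cleanly", {
  expect_error(nb_fit(matrix(1:6, ncol = 1), rep("a", 6)), "two classes")
  expect_error(nb_fit(matrix(1:6, ncol = 1), c("a", "a", "a", "a", "a", "b")),
               ">= 2 trials")
  m <- nb_fit(matrix(rnorm(8), ncol = 1), rep(c("rest", "left"), each = 4))
  expect_error(nb_predict(m, NaN), "non-finite")
})
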