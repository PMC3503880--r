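sinusoid_recording <- function(freq, fs = 256, dur = 12, channels = "ch1") {
  tt <- seq(1 / fs, dur, by = 1 / fs)
  d <- matrix(rep(sin(2 * pi * freq * tt), length(channels)),
              ncol = length(channels), dimnames = list(NULL, channels))
  eeg_recording(d, fs)
}

central_sd_ratio <- function(filtered, original, fs) {
  sel <- seq(2 * fs, nrow(filtered$data) - 2 * fs)
  sd(filtered$data[sel, 1]) / sd(original$data[sel, 1])
}

test_that("band-pass filter: passband flat, stopbands attenuated, zero phase", {
  for (fs in c(256, 100)) {
    r10 <- sinusoid_recording(10, fs = fs)
    f10 <- bandpass_filter(r10, 1, 40)
    expect_gt(central_sd_ratio(f10, r10, fs), 0.95)   # < 5% attenuation
    # zero phase: lag-0 correlation is the maximum
    sel <- seq(2 * fs, nrow(r10$data) - 2 * fs)
    cc <- ccf(f10$data[sel, 1], r10$data[sel, 1], lag.max = 5, plot = FALSE)
    expect_equal(cc$lag[which.max(cc$acf)], 0)

    r02 <- sinusoid_recording(0.2, fs = fs)
    expect_lt(central_sd_ratio(bandpass_filter(r02, 1, 40), r02, fs), 0.10)
  }
  r60 <- sinusoid_recording(60, fs = 256)
  expect_lt(central_sd_ratio(bandpass_filter(r60, 1, 40), r60, 256), 0.10)
})

test_that("filter refuses recordings shorter than three filter orders", {
  short <- eeg_recording(matrix(rnorm(600), ncol = 1), 256)
  expect_error(bandpass_filter(short, 1, 40), "too short")
})

test_that("resampling 256 -> 100 Hz preserves duration, tones and events", {
  r <- sinusoid_recording(10, fs = 256, dur = 10)
  r$events <- data.frame(onset_sample = 256L, condition = "left",
                         stringsAsFactors = FALSE)
  rr <- resample_recording(r, 100)
  expect_equal(nrow(rr$data), 1000)
  expect_equal(rr$srate, 100)
  # tone amplitude within 2% in the central region
  sel <- 200:800
  expect_lt(abs(sd(rr$data[sel, 1]) / sd(r$data[, 1]) - 1), 0.02)
  # event at sample 256 (t = 1 s) maps to sample 100
  expect_equal(rr$events$onset_sample, 100L)
})

test_that("epoching yields offset-relative 6 s trials and drops edge events", {
  fs <- 100
  n <- 5000
  d <- matrix(7, n, 2, dimnames = list(NULL, c("a", "b")))
  ev <- data.frame(onset_sample = c(100L, 1000L, n - 1L),
                   condition = c("left", "rest", "right"),
                   stringsAsFactors = FALSE)
  rec <- eeg_recording(d, fs, ev)
  expect_warning(ep <- epoch_recording(rec), "dropped")
  expect_equal(dim(ep$data), c(2, 2, 600))
  expect_equal(ep$conditions, c("left", "rest"))
  expect_equal(ep$time[1], -2)
  expect_equal(ep$time[600], 3.99)
  expect_true(all(ep$data == 7))   # constant channel stays constant
})

test_that("bipolar derivation is exact, label-based and reference-free", {
  fs <- 100
  tt <- seq(0, by = 1 / fs, length.out = 600) - 2
  chans <- c("FC3", "CP3", "FC4", "CP4", "Cz")
  d <- array(0, c(3, 5, 600), dimnames = list(NULL, chans, NULL))
  s10 <- sin(2 * pi * 10 * tt)
  for (tr in 1:3) {
    d[tr, "FC3", ] <- s10
    d[tr, "CP3", ] <- 0
    d[tr, "FC4", ] <- s10
    d[tr, "CP4", ] <- s10          # FC4 = CP4 -> C4' identically zero
  }
  ep <- eeg_epochs(d, fs, rep("rest", 3), tt)
  bp <- rereference_bipolar(ep)
  expect_equal(bp$channels, c("C3'", "C4'"))
  expect_equal(bp$data[1, 1, ], s10)
  expect_true(all(bp$data[, 2, ] == 0))
  expect_identical(bp$montage, "bipolar")

  # permuting input channel order changes nothing (label lookup)
  perm <- sample(5)
  ep2 <- eeg_epochs(d[, perm, , drop = FALSE], fs, rep("rest", 3), tt)
  expect_equal(rereference_bipolar(ep2)$data, bp$data)

  # adding a common signal to every channel cancels exactly
  common <- cos(2 * pi * 3 * tt)
  d3 <- d
  for (ci in 1:5) d3[, ci, ] <- sweep(d3[, ci, , drop = TRUE], 2, -common)
  ep3 <- eeg_epochs(d3, fs, rep("rest", 3), tt)
  expect_equal(rereference_bipolar(ep3)$data, bp$data)

  # missing electrode is named in the error
  ep4 <- eeg_epochs(d[, c("FC3", "CP3", "Cz"), , drop = FALSE], fs,
                    rep("rest", 3), tt)
  expect_error(rereference_bipolar(ep4), "FC4")
})

test_that("trial-count matching hits exact targets, errors on deficit", {
  ep <- simulate_responder_epochs(seed = 41, depth = 0, n_blocks = 2,
                                  match_counts = NULL)
  m <- match_trial_counts(ep, c(left = 20, right = 18, rest = 24), seed = 1)
  expect_equal(as.integer(table(m$conditions)[c("left", "right", "rest")]),
               c(20, 18, 24))
  # identity when targets equal availability
  avail <- table(ep$conditions)
  m2 <- match_trial_counts(ep, c(left = avail[["left"]],
                                 right = avail[["right"]],
                                 rest = avail[["rest"]]), seed = 1)
  expect_equal(m2$data, ep$data)
  # determinism
  expect_equal(match_trial_counts(ep, c(left = 20, rest = 20), seed = 5)$data,
               match_trial_counts(ep, c(left = 20, rest = 20), seed = 5)$data)
  expect_error(match_trial_counts(ep, c(left = 999), seed = 1), "deficit")
})

test_that("filter-then-resample and resample-then-filter agree in epoch cores", {
  cfg <- sim_config(n_blocks = 1, artifact_rate = 0, seed = 51)
  rec <- simulate_recording(cfg)
  a <- bandpass_filter(resample_recording(rec, 100), 1, 40)
  b <- resample_recording(bandpass_filter(rec, 1, 40), 100)
  ep_a <- epoch_recording(a)
  ep_b <- epoch_recording(b)
  core <- ep_a$time >= -1.5 & ep_a$time <= 3.5   # central 5 s
  xa <- ep_a$data[, , core]
  xb <- ep_b$data[, , core]
  expect_lt(sqrt(mean((xa - xb)^2)) / sqrt(mean(xa^2)), 0.01)
})
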