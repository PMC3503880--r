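test_that("simulation is bit-identical for identical config and seed", {
  cfg <- sim_config(n_blocks = 1, artifact_rate = 0.1, seed = 5,
                    effects = list(effect_spec("left", c(25, 30), 1)))
  r1 <- simulate_recording(cfg)
  r2 <- simulate_recording(cfg)
  expect_identical(r1$data, r2$data)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$ground_truth$artifact_trials,
                   r2$ground_truth$artifact_trials)
})

test_that("recording covers the schedule with >= 2 s padding on both ends", {
  cfg <- sim_config(n_blocks = 1, artifact_rate = 0, seed = 3)
  rec <- simulate_recording(cfg)
  sched <- rec$ground_truth$schedule
  fs <- rec$srate
  expect_gte(min(rec$events$onset_sample) / fs, 2)
  expect_gte(nrow(rec$data) / fs, max(sched$onset_time) + 6 + 2)
})

test_that("an ERS effect raises band power on matching trials and channel", {
  # depth +1.0, 25-30 Hz, left-hand trials, ipsilateral (left) hemisphere
  cfg <- sim_config(n_blocks = 1, artifact_rate = 0, seed = 11,
                    effects = list(effect_spec("left", c(25, 30), 1.0,
                                               latency = 1, duration = 1)))
  rec <- simulate_recording(cfg)
  ep <- epoch_recording(rec)
  sel <- rec$ground_truth$schedule$condition
  w_left <- welch_spectrum(subset_trials(ep, which(sel == "left")))
  w_rest <- welch_spectrum(subset_trials(ep, which(sel == "rest")))
  band <- w_left$freqs >= 25 & w_left$freqs <= 30
  for (ch in c("FC3", "C3")) {
    ci <- match(ch, ep$channels)
    expect_gt(mean(w_left$power[ci, band]), mean(w_rest$power[ci, band]))
  }
  # right hemisphere untouched by the left-hand ipsilateral effect
  ci <- match("FC4", ep$channels)
  expect_lt(abs(log(mean(w_left$power[ci, band]) /
                      mean(w_rest$power[ci, band]))), 0.5)
})

test_that("zero-depth effects leave conditions statistically indistinguishable", {
  # per-trial 25-30 Hz bandpower, left vs rest t-test non-significant at
  # alpha=.01 in >= 95% of seeded runs (100 runs, one block each)
  nonsig <- vapply(1:100, function(seed) {
    cfg <- sim_config(n_blocks = 1, artifact_rate = 0, seed = 3000 + seed)
    rec <- simulate_recording(cfg)
    ep <- epoch_recording(rec)
    tfr <- compute_tfr(ep, freqs = 25:30)
    bp <- apply(tfr$power[, match("FC3", ep$channels), , ], 1, mean)
    conds <- ep$conditions
    t.test(log(bp[conds == "left"]), log(bp[conds == "rest"]))$p.value > 0.01
  }, TRUE)
  expect_gte(mean(nonsig), 0.95)
})

test_that("artifact annotation count is binomial and deterministic", {
  cfg <- sim_config(n_blocks = 5, artifact_rate = 0.1, seed = 21)
  rec <- simulate_recording(cfg)
  n_art <- length(rec$ground_truth$artifact_trials)
  # ~Binomial(180, .1): central 99.9% mass
  expect_gte(n_art, qbinom(0.0005, 180, 0.1))
  expect_lte(n_art, qbinom(0.9995, 180, 0.1))
  expect_identical(simulate_recording(cfg)$ground_truth$artifact_trials,
                   rec$ground_truth$artifact_trials)
})

test_that("background spectral slope recovers the configured 1/f exponent", {
  for (a in c(0.8, 1.4)) {
    cfg <- sim_config(n_blocks = 1, artifact_rate = 0, seed = 31,
                      noise = noise_spec(one_over_f_exponent = a,
                                         broadband_sd = 5,
                                         oscillators = list()))
    rec <- simulate_recording(cfg)
    w <- welch_spectrum(epoch_recording(rec))
    sel <- w$freqs >= 2 & w$freqs <= 40
    slope <- unname(coef(lm(log10(w$power[1, sel]) ~ log10(w$freqs[sel])))[2])
    expect_lt(abs(-slope - a), 0.3)
  }
})

test_that("effects with no overlapping oscillator are rejected", {
  expect_error(
    simulate_recording(sim_config(
      n_blocks = 1, seed = 1,
      effects = list(effect_spec("left", c(35, 39), 1)))),
    "overlaps no oscillator")
})

test_that("effect_spec validates direction/depth consistency", {
  expect_error(effect_spec("left", c(25, 30), 1, direction = "ERD"),
               "inconsistent")
  expect_silent(effect_spec("left", c(25, 30), -0.5, direction = "ERD"))
  expect_error(effect_spec("left", c(25, 30), -1.2))
})
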