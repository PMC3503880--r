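# Shared fixture builders. Everything is generated in code at test time;
# no binary fixtures.

with_seed <- smrdetect:::with_seed

# i.i.d.-noise feature tensor shaped like the real extractor's output
# (trials x 100 time-points x 8 features).
make_null_features <- function(seed, n = 70, T = 100, P = 8,
                               conditions = rep(c("left", "rest"),
                                                c(ceiling(n / 2),
                                                  floor(n / 2)))) {
  with_seed(seed, {
    vals <- array(rnorm(n * T * P), c(n, T, P))
    if (P == 8) {
      dimnames(vals) <- list(NULL, NULL, as.vector(vapply(
        c("C3'", "C4'"),
        function(ch) paste(ch, names(smr_bands), sep = "_"),
        character(4))))
    }
    structure(list(values = vals,
                   times = seq(-1, by = 0.05, length.out = T),
                   bands = smr_bands,
                   channels = c("C3'", "C4'"),
                   conditions = conditions),
              class = "feature_tensor")
  })
}

# Epochs holding a single known waveform on every trial/channel.
make_waveform_epochs <- function(waveform_fn, n_trials = 4, srate = 100,
                                 channels = c("C3'", "C4'"),
                                 montage = "bipolar", noise_sd = 0,
                                 seed = 1) {
  tt <- seq(0, by = 1 / srate, length.out = 6 * srate) - 2
  with_seed(seed, {
    d <- array(0, c(n_trials, length(channels), length(tt)),
               dimnames = list(NULL, channels, NULL))
    for (tr in seq_len(n_trials)) {
      for (ci in seq_along(channels)) {
        d[tr, ci, ] <- waveform_fn(tt) + rnorm(length(tt), 0, noise_sd)
      }
    }
    eeg_epochs(d, srate, rep("rest", n_trials), tt, montage = montage)
  })
}

# One standard "responder" simulation: high-beta ipsilateral ERS on
# left-hand trials (the canonical ground-truth effect), preprocessed to
# clean bipolar epochs matched to the reference 36/33/34 trial counts.
simulate_responder_epochs <- function(seed, depth = 1.0, n_blocks = 3,
                                      artifact_rate = 0,
                                      match_counts = c(left = 36, right = 33,
                                                       rest = 34)) {
  effects <- if (depth != 0) {
    list(effect_spec("left", c(25, 30), depth, latency = 1, duration = 1))
  } else list()
  cfg <- sim_config(n_blocks = n_blocks, artifact_rate = artifact_rate,
                    effects = effects, seed = seed)
  rec <- simulate_recording(cfg)
  rec <- bandpass_filter(resample_recording(rec, 100), 1, 40)
  ep <- rereference_bipolar(epoch_recording(rec))
  if (!is.null(match_counts)) {
    ep <- match_trial_counts(ep, match_counts, seed = seed + 1L)
  }
  ep
}

# Pure-R reference cross-validation (independent oracle for the compiled
# inner loop): plain loops over folds and time-points through the public
# nb_fit()/nb_predict().
ref_cv_accuracy <- function(features, labels, folds) {
  k <- max(folds)
  n <- dim(features$values)[1]
  T <- dim(features$values)[2]
  acc <- matrix(0, k, T)
  for (f in seq_len(k)) {
    train <- which(folds != f)
    test <- which(folds == f)
    for (t in seq_len(T)) {
      X <- matrix(features$values[, t, ], nrow = n)
      m <- nb_fit(X[train, , drop = FALSE], labels[train])
      pred <- nb_predict(m, X[test, , drop = FALSE])$class
      acc[f, t] <- mean(pred == labels[test])
    }
  }
  colMeans(acc)
}

# Closed-form two-Gaussian Bayes posterior for one feature.
closed_form_posterior <- function(x, m0, s0, m1, s1, p0, p1) {
  d0 <- p0 * dnorm(x, m0, s0)
  d1 <- p1 * dnorm(x, m1, s1)
  d1 / (d0 + d1)
}
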