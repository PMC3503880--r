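#' Band-limited oscillator specification
#'
#' One stochastic narrow-band source (e.g. a mu or beta idling rhythm)
#' projected onto the scalp channels with fixed weights. The source is
#' band-limited Gaussian noise on `[center - bandwidth/2, center +
#' bandwidth/2]` scaled to `amplitude` microvolts RMS; weights differ
#' across the FC/CP pair so the rhythm survives the bipolar derivation.
#'
#' @param center Center frequency, Hz.
#' @param bandwidth Full bandwidth, Hz.
#' @param amplitude Source RMS amplitude, microvolts.
#' @param weights Named numeric vector of channel projection weights.
#' @export
oscillator <- function(center, bandwidth, amplitude, weights) {
  stopifnot(center > 0, bandwidth > 0, amplitude >= 0,
            length(weights) > 0, !is.null(names(weights)),
            all(is.finite(weights)))
  structure(list(center = center, bandwidth = bandwidth,
                 amplitude = amplitude, weights = weights),
            class = "smr_oscillator")
}

#' Default mu/beta oscillators for the 9-channel montage
#'
#' One mu (10 Hz) and one high-beta (27.5 Hz) source per hemisphere.
#' Amplitudes are documented modelling assumptions, not estimates of any
#' individual: the bedside recordings behind the method are not deposited.
#' @param mu_amplitude,beta_amplitude Source RMS amplitudes, microvolts.
#' @export
default_oscillators <- function(mu_amplitude = 2, beta_amplitude = 1.5) {
  w_left <- c(FC3 = 1, C3 = 0.7, CP3 = 0.3)
  w_right <- c(FC4 = 1, C4 = 0.7, CP4 = 0.3)
  list(
    oscillator(10, 4, mu_amplitude, w_left),
    oscillator(10, 4, mu_amplitude, w_right),
    oscillator(27.5, 5, beta_amplitude, w_left),
    oscillator(27.5, 5, beta_amplitude, w_right)
  )
}

#' Background noise specification
#'
#' @param one_over_f_exponent Spectral exponent a of the 1/f^a background
#'   power spectrum (amplitude falls as f^(-a/2)).
#' @param broadband_sd Per-channel standard deviation of the background,
#'   microvolts.
#' @param oscillators List of [oscillator()] objects.
#' @param delta_boost Optional named numeric vector of per-channel
#'   amplitude multipliers applied to the background below 4 Hz (models
#'   pathologically lateralized delta power).
#' @export
noise_spec <- function(one_over_f_exponent = 1,
                       broadband_sd = 5,
                       oscillators = default_oscillators(),
                       delta_boost = NULL) {
  stopifnot(broadband_sd >= 0,
            all(vapply(oscillators, inherits, TRUE, "smr_oscillator")))
  if (!is.null(delta_boost)) {
    stopifnot(!is.null(names(delta_boost)), all(delta_boost >= 0))
  }
  structure(list(one_over_f_exponent = one_over_f_exponent,
                 broadband_sd = broadband_sd,
                 oscillators = oscillators,
                 delta_boost = delta_boost),
            class = "smr_noise_spec")
}

#' Event-locked ERD/ERS effect specification
#'
#' A multiplicative amplitude envelope applied to the matching
#' oscillator(s) on trials of one condition. `depth` is the fractional
#' amplitude change at the plateau (+1 doubles the amplitude, i.e. an ERS;
#' -0.5 halves it, an ERD). The plateau starts `latency` seconds after
#' instruction *offset* and lasts `duration` seconds, with linear ramps of
#' `ramp` seconds on either side.
#'
#' Laterality follows the convention that attempted movement of one hand
#' produces an ipsilateral ERS: `channel_side = "ipsilateral"` for a
#' left-hand effect targets the left-hemisphere oscillators.
#'
#' @param condition "left" or "right".
#' @param band Length-2 numeric (f_lo, f_hi) in Hz; must overlap at least
#'   one oscillator's band.
#' @param depth Fractional amplitude change, > -1.
#' @param channel_side "ipsilateral", "contralateral" or "both".
#' @param latency,duration,ramp Seconds (see above).
#' @param direction Optional "ERD"/"ERS" label; must agree with the sign
#'   of `depth` if given.
#' @export
effect_spec <- function(condition, band, depth,
                        channel_side = c("ipsilateral", "contralateral", "both"),
                        latency = 1, duration = 1, ramp = 0.25,
                        direction = NULL) {
  channel_side <- match.arg(channel_side)
  stopifnot(condition %in% c("left", "right"),
            length(band) == 2, band[1] > 0, band[1] < band[2],
            depth > -1, duration > 0, ramp >= 0)
  if (!is.null(direction)) {
    direction <- match.arg(direction, c("ERD", "ERS"))
    if (direction == "ERS" && depth <= 0 || direction == "ERD" && depth >= 0) {
      stop("direction '", direction, "' inconsistent with depth ", depth)
    }
  } else {
    direction <- if (depth >= 0) "ERS" else "ERD"
  }
  structure(list(condition = condition, channel_side = channel_side,
                 band = band, direction = direction, depth = depth,
                 latency = latency, duration = duration, ramp = ramp),
            class = "smr_effect_spec")
}

#' Simulation configuration
#'
#' @param n_blocks Number of 36-trial blocks (5 = the full session).
#' @param channels Channel labels (default: the 9-electrode montage).
#' @param sampling_rate Hz; must exceed twice the highest oscillator
#'   frequency.
#' @param noise A [noise_spec()].
#' @param effects List of [effect_spec()] objects (ground-truth ERD/ERS).
#' @param artifact_rate Fraction of trials receiving a broadband muscle
#'   artifact burst. The default mirrors the roughly 43% trial loss of the
#'   bedside recording that motivated the automated rejection rule.
#' @param artifact_snr_range Burst amplitude, as a multiple of
#'   `broadband_sd` (uniform draw per artifact).
#' @param artifact_duration_range Burst duration bounds, seconds.
#' @param artifact_band Burst frequency band, Hz.
#' @param pad Seconds of signal before the first instruction and after the
#'   last epoch (supports filter transients).
#' @param seed Integer seed; the simulation is fully deterministic given
#'   the config.
#' @export
sim_config <- function(n_blocks = 5, channels = smr_channels,
                       sampling_rate = 256,
                       noise = noise_spec(),
                       effects = list(),
                       artifact_rate = 0.4,
                       artifact_snr_range = c(5, 10),
                       artifact_duration_range = c(0.5, 1.5),
                       artifact_band = c(20, 100),
                       pad = 2, seed = 1) {
  stopifnot(n_blocks >= 1, sampling_rate > 0, pad >= 2,
            artifact_rate >= 0, artifact_rate <= 1,
            inherits(noise, "smr_noise_spec"),
            all(vapply(effects, inherits, TRUE, "smr_effect_spec")))
  f_max <- max(0, vapply(noise$oscillators,
                         function(o) o$center + o$bandwidth / 2, 0))
  if (sampling_rate <= 2 * f_max) {
    stop("sampling_rate must exceed twice the highest oscillator frequency")
  }
  if (max(artifact_band) >= sampling_rate / 2) {
    artifact_band[2] <- sampling_rate / 2 * 0.98
  }
  structure(list(n_blocks = n_blocks, channels = channels,
                 sampling_rate = sampling_rate, noise = noise,
                 effects = effects, artifact_rate = artifact_rate,
                 artifact_snr_range = artifact_snr_range,
                 artifact_duration_range = artifact_duration_range,
                 artifact_band = artifact_band,
                 pad = pad, seed = as.integer(seed)),
            class = "smr_sim_config")
}

# Real-valued noise with spectral amplitude profile amp_fn(f); length n.
spectral_noise <- function(n, fs, amp_fn) {
  nfft <- stats::nextn(n, c(2L, 3L, 5L))
  while (nfft %% 2L == 1L) nfft <- stats::nextn(nfft + 1L, c(2L, 3L, 5L))
  half <- nfft %/% 2L
  f <- (0:half) * fs / nfft
  a <- amp_fn(f)
  a[!is.finite(a)] <- 0
  z <- complex(real = rnorm(half + 1L), imaginary = rnorm(half + 1L)) * a
  z[1L] <- 0
  z[half + 1L] <- complex(real = Re(z[half + 1L]), imaginary = 0)
  spec <- c(z, Conj(z[half:2L]))
  x <- Re(fft(spec, inverse = TRUE)) / nfft
  x[seq_len(n)]
}

# Scale a vector to an exact standard deviation (no-op for zero target).
scale_to_sd <- function(x, target) {
  s <- stats::sd(x)
  if (s == 0 || target == 0) return(x * 0)
  x * (target / s)
}

# Hemisphere of an oscillator, inferred from its projection weights.
osc_side <- function(osc) {
  labs <- names(osc$weights)
  wl <- sum(abs(osc$weights[grepl("3$", labs)]))
  wr <- sum(abs(osc$weights[grepl("4$", labs)]))
  if (wl > wr) "left" else if (wr > wl) "right" else "mid"
}

# Resolve an effect's channel_side to hemisphere labels, under the
# convention that the attempted hand's ipsilateral hemisphere carries the
# ERS (left hand -> left-hemisphere channels).
effect_hemispheres <- function(effect) {
  ipsi <- effect$condition                 # left hand -> left hemisphere
  contra <- setdiff(c("left", "right"), ipsi)
  switch(effect$channel_side,
         ipsilateral = ipsi,
         contralateral = contra,
         both = c("left", "right", "mid"))
}

bands_overlap <- function(b1, b2) max(b1[1], b2[1]) < min(b1[2], b2[2])

# Add one plateau-with-ramps bump (multiplicative factor 1 -> 1+depth) to
# an envelope vector, in place arithmetic on a copy.
apply_bump <- function(env, fs, t0, duration, ramp, depth) {
  n <- length(env)
  t_up0 <- t0 - ramp
  t_dn1 <- t0 + duration + ramp
  i0 <- max(1L, floor(t_up0 * fs) + 1L)
  i1 <- min(n, ceiling(t_dn1 * fs) + 1L)
  if (i1 < i0) return(env)
  t <- (seq(i0, i1) - 1) / fs
  frac <- rep(1, length(t))
  if (ramp > 0) {
    frac <- pmin(1, pmax(0, pmin((t - t_up0) / ramp, (t_dn1 - t) / ramp)))
  } else {
    frac <- as.numeric(t >= t0 & t <= t0 + duration)
  }
  env[i0:i1] <- env[i0:i1] * (1 + depth * frac)
  env
}

#' Simulate a task EEG recording with known ERD/ERS ground truth
#'
#' Generates the instruction schedule, a 1/f background plus band-limited
#' mu/beta oscillators per hemisphere, event-locked multiplicative ERD/ERS
#' envelopes on the matching oscillators, and optional broadband muscle
#' artifact bursts on a random subset of trials. Identical config (incl.
#' seed) gives bit-identical output.
#'
#' @param config A [sim_config()].
#' @return An [eeg_recording()] with an extra element `ground_truth`:
#'   a list with the `schedule`, the indices of `artifact_trials`, and the
#'   realized `effects`.
#' @export
simulate_recording <- function(config) {
  stopifnot(inherits(config, "smr_sim_config"))
  fs <- config$sampling_rate
  seeds <- derive_seeds(config$seed,
                        c("schedule", "background", "oscillators",
                          "artifacts"))
  sched <- generate_schedule(config$n_blocks, seed = seeds[["schedule"]],
                             start_time = config$pad)
  total_s <- max(sched$onset_time) + 6 + config$pad
  n <- ceiling(total_s * fs)
  nois <- config$noise
  chans <- config$channels

  # effect -> oscillator matching (validated up front)
  osc_sides <- vapply(nois$oscillators, osc_side, "")
  osc_bands <- lapply(nois$oscillators,
                      function(o) c(o$center - o$bandwidth / 2,
                                    o$center + o$bandwidth / 2))
  match_tbl <- lapply(config$effects, function(ef) {
    hemis <- effect_hemispheres(ef)
    hit <- which(vapply(seq_along(nois$oscillators), function(i) {
      bands_overlap(ef$band, osc_bands[[i]]) && osc_sides[i] %in% hemis
    }, TRUE))
    if (length(hit) == 0) {
      stop(sprintf(
        "effect (%s, %s, %g-%g Hz) overlaps no oscillator band on that side",
        ef$condition, ef$channel_side, ef$band[1], ef$band[2]))
    }
    hit
  })

  data <- matrix(0, n, length(chans), dimnames = list(NULL, chans))

  # 1/f^a background, independent per channel; optional delta boost
  with_seed(seeds[["background"]], {
    a_exp <- nois$one_over_f_exponent
    for (ci in seq_along(chans)) {
      boost <- 1
      if (!is.null(nois$delta_boost) && chans[ci] %in% names(nois$delta_boost)) {
        boost <- nois$delta_boost[[chans[ci]]]
      }
      amp_fn <- local({
        bst <- boost
        function(f) ifelse(f >= 0.5, f^(-a_exp / 2), 0) *
          ifelse(f < 4, bst, 1)
      })
      data[, ci] <- scale_to_sd(spectral_noise(n, fs, amp_fn),
                                nois$broadband_sd)
    }
  })

  # oscillators with event-locked multiplicative envelopes
  with_seed(seeds[["oscillators"]], {
    for (oi in seq_along(nois$oscillators)) {
      osc <- nois$oscillators[[oi]]
      band <- osc_bands[[oi]]
      src <- scale_to_sd(
        spectral_noise(n, fs, function(f)
          as.numeric(f >= band[1] & f <= band[2])),
        osc$amplitude)
      env <- rep(1, n)
      for (ei in seq_along(config$effects)) {
        ef <- config$effects[[ei]]
        if (!(oi %in% match_tbl[[ei]])) next
        trials <- which(sched$condition == ef$condition)
        for (tr in trials) {
          offset_t <- sched$onset_time[tr] + sched$instruction_duration[tr]
          env <- apply_bump(env, fs, offset_t + ef$latency,
                            ef$duration, ef$ramp, ef$depth)
        }
      }
      src <- src * env
      present <- intersect(names(osc$weights), chans)
      for (lab in present) {
        data[, lab] <- data[, lab] + osc$weights[[lab]] * src
      }
    }
  })

  # broadband muscle artifact bursts on a random subset of trials
  artifact_trials <- integer(0)
  with_seed(seeds[["artifacts"]], {
    if (config$artifact_rate > 0) {
      hit <- which(rbinom(nrow(sched), 1, config$artifact_rate) == 1)
      artifact_trials <- hit
      for (tr in hit) {
        dur <- runif(1, config$artifact_duration_range[1],
                     config$artifact_duration_range[2])
        t0 <- runif(1, sched$onset_time[tr],
                    sched$onset_time[tr] + 6 - dur)
        amp <- runif(1, config$artifact_snr_range[1],
                     config$artifact_snr_range[2]) * nois$broadband_sd
        i0 <- floor(t0 * fs) + 1L
        nb <- max(2L, round(dur * fs))
        i1 <- min(n, i0 + nb - 1L)
        nb <- i1 - i0 + 1L
        taper_len <- max(1L, round(0.05 * fs))
        taper <- rep(1, nb)
        ramp_idx <- seq_len(min(taper_len, nb))
        taper[ramp_idx] <- seq(0, 1, length.out = length(ramp_idx))
        taper[nb + 1L - ramp_idx] <- pmin(taper[nb + 1L - ramp_idx],
                                          seq(0, 1, length.out = length(ramp_idx)))
        bb <- config$artifact_band
        for (ci in seq_along(chans)) {
          burst <- scale_to_sd(
            spectral_noise(nb, fs, function(f)
              as.numeric(f >= bb[1] & f <= bb[2])), amp)
          data[i0:i1, ci] <- data[i0:i1, ci] + burst * taper
        }
      }
    }
  })

  events <- data.frame(
    onset_sample = as.integer(round(sched$onset_time * fs)),
    condition = sched$condition,
    stringsAsFactors = FALSE
  )
  rec <- eeg_recording(data, fs, events)
  rec$ground_truth <- list(schedule = sched,
                           artifact_trials = artifact_trials,
                           effects = config$effects)
  rec
}
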