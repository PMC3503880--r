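# Shared short-time Fourier machinery for the average-level TFR and the
# single-trial bandpower features. Windows are 1 s Hann, sliding in 50 ms
# steps, and labeled by their END time: a cell labeled t summarizes
# [t - 1 s, t]. On a 6 s epoch this yields labels -1.00 ... +3.95 s (100
# cells); the naive 101st window (ending exactly at +4.0 s) is dropped so
# the cell count matches the 100 time-points of the reference analysis.

stft_window_ends <- function(n_samp, srate, window = 1, step = 0.05) {
  w <- round(window * srate)
  s <- round(step * srate)
  ends <- seq(w, n_samp, by = s)
  if (length(ends) > 1 && ends[length(ends)] == n_samp) {
    ends <- ends[-length(ends)]
  }
  ends
}

# Power array (trials x channels x freqs x windows) for integer-Hz bins.
# With a 1 s window the FFT bin spacing is exactly 1 Hz. Power is scaled
# so a sinusoid of amplitude A at a bin frequency reads ~A^2/2 (its mean
# square), i.e. 2|X|^2 / (sum w)^2.
stft_power <- function(epochs, freqs, window = 1, step = 0.05) {
  fs <- epochs$srate
  wlen <- round(window * fs)
  ny <- fs / 2
  if (any(freqs > ny)) stop("requested frequency above Nyquist (", ny, " Hz)")
  d <- epochs$data
  nt <- dim(d)[1]; nc <- dim(d)[2]; ns <- dim(d)[3]
  if (ns < wlen) stop("epoch shorter than the analysis window")
  ends <- stft_window_ends(ns, fs, window, step)
  nw <- length(ends)
  win <- hann_window(wlen)
  wsum <- sum(win)
  seg_idx <- outer(seq_len(wlen) - wlen, ends, "+")   # wlen x nw
  bin <- round(freqs * window) + 1L                   # FFT bin per freq
  pow <- array(0, dim = c(nt, nc, length(freqs), nw))
  for (tr in seq_len(nt)) {
    for (ci in seq_len(nc)) {
      x <- d[tr, ci, ]
      segs <- matrix(x[seg_idx], wlen, nw) * win
      X <- stats::mvfft(segs)[bin, , drop = FALSE]
      pow[tr, ci, , ] <- 2 * (Mod(X)^2) / wsum^2
    }
  }
  times <- epochs$time[1] + ends / fs   # end-labeled, in epoch time
  list(power = pow, freqs = freqs, times = times)
}

#' Time-frequency transformation (fixed 1 s Hann window)
#'
#' Per-trial spectral power at 1 Hz resolution from a fixed-length (1 s,
#' Hann) sliding window moving in 50 ms steps. Cells are labeled by window
#' END time, spanning -1.0 to +3.95 s relative to instruction offset on a
#' standard 6 s epoch (100 cells).
#'
#' @param epochs An [eeg_epochs()].
#' @param freqs Integer frequencies in Hz (default 1--40).
#' @param window Window length, seconds.
#' @param step Window step, seconds.
#' @return An object of class `eeg_tfr`: list with `power`
#'   (trials x channels x freqs x times), `freqs`, `times`, `channels`,
#'   `conditions`.
#' @export
compute_tfr <- function(epochs, freqs = 1:40, window = 1, step = 0.05) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  st <- stft_power(epochs, freqs, window, step)
  structure(list(power = st$power, freqs = st$freqs, times = st$times,
                 channels = epochs$channels,
                 conditions = epochs$conditions,
                 srate = epochs$srate),
            class = "eeg_tfr")
}

#' @export
print.eeg_tfr <- function(x, ...) {
  cat(sprintf("<eeg_tfr> %d trials x %d channels, %d freqs (%g-%g Hz) x %d time cells (%g to %g s)\n",
              dim(x$power)[1], dim(x$power)[2], length(x$freqs),
              min(x$freqs), max(x$freqs), length(x$times),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Subset a TFR by trial index
#' @param tfr An `eeg_tfr`.
#' @param idx Trial indices to keep.
#' @export
subset_tfr_trials <- function(tfr, idx) {
  out <- tfr
  out$power <- tfr$power[idx, , , , drop = FALSE]
  out$conditions <- tfr$conditions[idx]
  out
}

#' Log power ratio between two conditions
#'
#' Elementwise `log(mean power A / mean power B)` over trials, per
#' (channel, frequency, time) cell — the quantity usually mapped when
#' visualizing ERD/ERS against rest. Antisymmetric under operand swap.
#'
#' @param tfr_active,tfr_rest `eeg_tfr` objects with matching axes.
#' @return Array channels x freqs x times of log ratios.
#' @export
contrast_log_ratio <- function(tfr_active, tfr_rest) {
  stopifnot(inherits(tfr_active, "eeg_tfr"), inherits(tfr_rest, "eeg_tfr"),
            identical(tfr_active$freqs, tfr_rest$freqs),
            identical(tfr_active$times, tfr_rest$times),
            identical(tfr_active$channels, tfr_rest$channels))
  ma <- apply(tfr_active$power, c(2, 3, 4), mean)
  mr <- apply(tfr_rest$power, c(2, 3, 4), mean)
  if (any(ma == 0) || any(mr == 0)) {
    stop("zero mean power cell; log ratio undefined")
  }
  lr <- log(ma / mr)
  dimnames(lr) <- list(tfr_active$channels, tfr_active$freqs, NULL)
  lr
}
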