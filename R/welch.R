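#' Whole-epoch Welch power spectrum
#'
#' Average (non-time-varying) power spectral density across entire
#' epochs, mirroring the default sectioning of MATLAB's pwelch as used
#' for clinical-style spectra: each epoch is divided into 8 sections of
#' length `floor(N / 4.5)` with 50% overlap, each section is
#' Hamming-windowed and its periodogram computed (zero-padded to
#' `nfft`), the 8 periodograms are averaged, then averaged across trials
#' and reported in dB (10 log10).
#'
#' @param epochs An [eeg_epochs()].
#' @param condition Optional condition label; if given, only those trials
#'   contribute.
#' @param nfft FFT length (default `max(256, next power of 2 >= section)`).
#' @return Object of class `welch_spectrum`: `power_db` (channels x
#'   freqs), `power` (linear, microvolts^2/Hz), `freqs`, `condition`,
#'   `n_trials`, `scheme`.
#' @export
welch_spectrum <- function(epochs, condition = NULL, nfft = NULL) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (!is.null(condition)) {
    idx <- which(epochs$conditions == condition)
    if (length(idx) == 0) stop("no trials of condition '", condition, "'")
    epochs <- subset_trials(epochs, idx)
  }
  d <- epochs$data
  fs <- epochs$srate
  nt <- dim(d)[1]; nc <- dim(d)[2]; ns <- dim(d)[3]
  L <- floor(ns / 4.5)
  if (L < 2) stop("epoch too short for Welch sectioning")
  hop <- floor(L / 2)
  nsec <- 1L + floor((ns - L) / hop)
  starts <- (0:(nsec - 1L)) * hop + 1L
  if (is.null(nfft)) nfft <- max(256L, 2^ceiling(log2(L)))
  win <- hamming_window(L)
  U <- sum(win^2)                      # window energy (PSD normalization)
  nfreq <- nfft %/% 2L + 1L
  freqs <- (0:(nfreq - 1L)) * fs / nfft

  acc <- matrix(0, nc, nfreq)
  for (tr in seq_len(nt)) {
    for (ci in seq_len(nc)) {
      x <- d[tr, ci, ]
      segs <- vapply(starts, function(s0) {
        c(x[s0:(s0 + L - 1L)] * win, rep(0, nfft - L))
      }, numeric(nfft))
      P <- Mod(stats::mvfft(segs))^2 / (fs * U)
      p1 <- rowMeans(P)[seq_len(nfreq)]
      # one-sided: double everything except DC (and Nyquist if present)
      dbl <- rep(2, nfreq); dbl[1] <- 1
      if (nfft %% 2L == 0L) dbl[nfreq] <- 1
      acc[ci, ] <- acc[ci, ] + p1 * dbl
    }
  }
  pw <- acc / nt
  structure(list(power_db = 10 * log10(pmax(pw, .Machine$double.xmin)),
                 power = pw, freqs = freqs,
                 condition = condition %||% "all",
                 n_trials = nt,
                 channels = epochs$channels,
                 scheme = list(n_sections = nsec, section_length = L,
                               overlap = L - hop, window = "hamming",
                               nfft = nfft)),
            class = "welch_spectrum")
}

#' @export
print.welch_spectrum <- function(x, ...) {
  cat(sprintf("<welch_spectrum> condition '%s', %d trials, %d channels, %d sections of %d samples\n",
              x$condition, x$n_trials, length(x$channels),
              x$scheme$n_sections, x$scheme$section_length))
  invisible(x)
}
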