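# -- FIR design and zero-phase filtering --------------------------------
#
# No FIR/filtfilt tooling ships with base R, so the package carries its
# own: linear-phase (type I) FIR design by least squares on a dense
# frequency grid against a piecewise-linear desired response (the classic
# firls behaviour that EEGLAB's pop_eegfilt relies on), applied forward-
# backward for zero phase.

.fir_cache <- new.env(parent = emptyenv())

# Least-squares linear-phase FIR. order must be even; freqs are
# band-edge frequencies normalized to [0, 1] (1 = Nyquist), amps the
# desired amplitude at each edge; the desired response is linear between
# consecutive edges (including transition bands), exactly as in firls.
fir_design_ls <- function(order, freqs, amps, grid_density = 16) {
  stopifnot(order %% 2 == 0, length(freqs) == length(amps),
            !is.unsorted(freqs), freqs[1] == 0, freqs[length(freqs)] == 1)
  key <- paste(c(order, signif(freqs, 10), amps), collapse = "_")
  hit <- .fir_cache[[key]]
  if (!is.null(hit)) return(hit)

  m <- order / 2
  npts <- max(512, grid_density * (m + 1))
  g <- seq(0, 1, length.out = npts)
  d <- stats::approx(freqs, amps, xout = g, ties = "ordered")$y
  w <- pi * g
  # A(w) = a0 + sum_k a_k cos(k w); solve min ||C a - d||
  C <- cbind(1, cos(outer(w, seq_len(m))))
  a <- stats::.lm.fit(C, d)$coefficients
  h <- c(rev(a[-1]) / 2, a[1], a[-1] / 2)
  .fir_cache[[key]] <- h
  h
}

# Linear convolution via FFT, returning the 'same'-size centered result.
conv_same <- function(x, h) {
  n <- length(x); l <- length(h)
  nfft <- stats::nextn(n + l - 1L, c(2L, 3L, 5L))
  y <- Re(fft(fft(c(x, rep(0, nfft - n))) *
                fft(c(h, rep(0, nfft - l))), inverse = TRUE)) / nfft
  delay <- (l - 1L) %/% 2L
  y[(delay + 1L):(delay + n)]
}

# Zero-phase FIR filtering. For a symmetric (linear-phase) kernel,
# forward-backward application equals one centered pass with h * h; edge
# transients are controlled by odd-reflection padding, as in filtfilt.
filtfilt_fir <- function(x, h) {
  n <- length(x)
  l <- length(h)
  npad <- min(n - 1L, 3L * l)
  pre <- 2 * x[1] - x[seq(npad + 1L, 2L, by = -1L)]
  post <- 2 * x[n] - x[seq(n - 1L, n - npad, by = -1L)]
  hh <- conv_full(h, h)
  y <- conv_same(c(pre, x, post), hh)
  y[(npad + 1L):(npad + n)]
}

conv_full <- function(a, b) {
  na <- length(a); nb <- length(b)
  nfft <- stats::nextn(na + nb - 1L, c(2L, 3L, 5L))
  Re(fft(fft(c(a, rep(0, nfft - na))) *
           fft(c(b, rep(0, nfft - nb))), inverse = TRUE))[seq_len(na + nb - 1L)] / nfft
}

# pop_eegfilt-style filter orders (even, for type-I symmetry).
fir_order_highpass <- function(fs, lo) {
  ord <- 3L * floor(fs / lo)
  ord + ord %% 2L
}
fir_order_lowpass <- function(fs, hi) {
  ord <- max(15L, 3L * floor(fs / (hi * 0.25)))
  ord + ord %% 2L
}

#' Zero-phase FIR band-pass filter
#'
#' Two-way (forward-backward) least-squares FIR filtering of a continuous
#' recording: first a high-pass at `lo` Hz, then a low-pass at `hi` Hz,
#' with 15% transition bands and filter orders following the common
#' EEGLAB heuristic (3 x rate/cutoff for the high-pass; at least 15 taps
#' for the low-pass). Zero phase: a pure passband sinusoid comes through
#' with no phase shift.
#'
#' @param raw An [eeg_recording()].
#' @param lo,hi Band edges in Hz.
#' @return The filtered [eeg_recording()], same length and events.
#' @export
bandpass_filter <- function(raw, lo = 1, hi = 40) {
  stopifnot(inherits(raw, "eeg_recording"), lo > 0, hi > lo)
  fs <- raw$srate
  if (fs <= 2 * hi) stop("sampling rate must exceed twice the low-pass cutoff")
  ny <- fs / 2
  trans <- 0.15
  ord_hp <- fir_order_highpass(fs, lo)
  ord_lp <- fir_order_lowpass(fs, hi)
  if (n_samples(raw) <= 3 * max(ord_hp, ord_lp)) {
    stop("recording too short for the filter order (need > ",
         3 * max(ord_hp, ord_lp), " samples)")
  }
  h_hp <- fir_design_ls(ord_hp,
                        c(0, lo * (1 - trans) / ny, lo / ny, 1),
                        c(0, 0, 1, 1))
  f_lp_hi <- min(hi * (1 + trans) / ny, 1)
  h_lp <- fir_design_ls(ord_lp,
                        unique(c(0, hi / ny, f_lp_hi, 1)),
                        if (f_lp_hi < 1) c(1, 1, 0, 0) else c(1, 1, 0))
  out <- raw
  for (ci in seq_len(ncol(raw$data))) {
    x <- filtfilt_fir(raw$data[, ci], h_hp)
    out$data[, ci] <- filtfilt_fir(x, h_lp)
  }
  out
}

# -- Rational-ratio resampling ------------------------------------------

# Polyphase upfirdn: upsample by L, FIR low-pass, downsample by M.
upfirdn_resample <- function(x, L, M, n_out, h) {
  D <- (length(h) - 1L) %/% 2L       # group delay on the upsampled grid
  y <- numeric(n_out)
  m_all <- seq_len(n_out) - 1L
  for (g in 0:(L - 1L)) {
    ms <- m_all[m_all %% L == g]
    if (length(ms) == 0) next
    u0 <- ms * M + D                  # upsampled center index per output
    r <- (g * M + D) %% L
    js <- seq(r, length(h) - 1L, by = L)
    for (j in js) {
      k <- (u0 - j) / L               # input sample index (0-based), exact
      ok <- k >= 0 & k <= length(x) - 1L
      if (!any(ok)) next
      y[ms[ok] + 1L] <- y[ms[ok] + 1L] + h[j + 1L] * x[k[ok] + 1L]
    }
  }
  y
}

#' Anti-aliased rational resampling
#'
#' Resamples a recording to `target` Hz by the rational factor L/M
#' (25/64 for 256 to 100 Hz) with a windowed-sinc anti-aliasing low-pass,
#' polyphase implementation. Event onsets are remapped by
#' `round(onset_sample * target / srate)` (half away from zero).
#'
#' @param raw An [eeg_recording()].
#' @param target Target sampling rate in Hz (must divide rationally into
#'   the original rate and be smaller than it).
#' @return The resampled [eeg_recording()].
#' @export
resample_recording <- function(raw, target = 100) {
  stopifnot(inherits(raw, "eeg_recording"), target > 0)
  fs <- raw$srate
  if (target >= fs) stop("target rate must be below the original rate")
  # rational factor from integer-scaled rates
  scale <- 1e6
  g <- gcd_int(round(target * scale), round(fs * scale))
  L <- round(target * scale) / g
  M <- round(fs * scale) / g
  n_in <- n_samples(raw)
  n_out <- ceiling(n_in * L / M)

  # windowed-sinc low-pass at the tighter of the two Nyquists, gain L
  half_len <- 10L * max(L, M)
  m <- seq(-half_len, half_len)
  fc <- 1 / max(L, M)                 # cutoff as fraction of upsampled Nyquist
  h <- fc * sinc(fc * m) * hamming_window(2L * half_len + 1L) * L

  out <- raw
  out$data <- matrix(0, n_out, ncol(raw$data),
                     dimnames = list(NULL, colnames(raw$data)))
  for (ci in seq_len(ncol(raw$data))) {
    out$data[, ci] <- upfirdn_resample(raw$data[, ci], L, M, n_out, h)
  }
  out$srate <- target
  if (nrow(raw$events) > 0) {
    out$events$onset_sample <-
      as.integer(pmin(n_out - 1L,
                      pmax(0, round_half_away(raw$events$onset_sample * L / M))))
  }
  out$channels <- colnames(out$data)
  out
}

gcd_int <- function(a, b) {
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

hamming_window <- function(n) {
  0.54 - 0.46 * cos(2 * pi * (0:(n - 1L)) / (n - 1L))
}

hann_window <- function(n) {
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1L)) / (n - 1L))
}
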