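#' Canonical sensorimotor frequency bands
#'
#' mu 7--13 Hz, low-beta 13--19 Hz, mid-beta 19--25 Hz, high-beta
#' 25--30 Hz. With 1 Hz STFT bins, shared band edges are assigned to the
#' lower-edge band (membership `lo <= f < hi`); the high-beta band keeps
#' its upper edge (25--30 inclusive).
#' @export
smr_bands <- list(mu = c(7, 13), low_beta = c(13, 19),
                  mid_beta = c(19, 25), high_beta = c(25, 30))

band_bins <- function(band_name, band, freqs) {
  if (band_name == "high_beta") {
    which(freqs >= band[1] & freqs <= band[2])
  } else {
    which(freqs >= band[1] & freqs < band[2])
  }
}

#' Sliding-window log bandpower features
#'
#' Classification features: natural-log bandpower in the four mu/beta
#' bands on the two bipolar channels, estimated with the same 1 s Hann
#' short-time Fourier transform as the average-level analysis (50 ms
#' steps, end-labeled windows, 100 time-points on a 6 s epoch). Power is
#' summed over the STFT bins inside each band before taking the log,
#' giving 8 features (2 channels x 4 bands) per time-point per trial.
#'
#' @param epochs A *bipolar* [eeg_epochs()] (the features are defined on
#'   C3'/C4').
#' @param bands Named list of (lo, hi) bands in Hz.
#' @return Object of class `feature_tensor`: `values` (trials x
#'   time-points x features), `times` (s, offset-relative), `bands`,
#'   `channels`, `conditions`.
#' @export
extract_bandpower <- function(epochs, bands = smr_bands) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (epochs$montage != "bipolar") {
    stop("bandpower features are defined on the bipolar montage; ",
         "call rereference_bipolar() first")
  }
  freqs <- seq(1, floor(max(vapply(bands, max, 0))))
  st <- stft_power(epochs, freqs)
  nt <- dim(st$power)[1]; nc <- dim(st$power)[2]; nw <- dim(st$power)[4]
  nb <- length(bands)
  vals <- array(0, dim = c(nt, nw, nc * nb))
  fnames <- character(nc * nb)
  k <- 0L
  for (ci in seq_len(nc)) {
    for (bi in seq_len(nb)) {
      k <- k + 1L
      bins <- band_bins(names(bands)[bi], bands[[bi]], freqs)
      bp <- apply(st$power[, ci, bins, , drop = FALSE], c(1, 4), sum)
      vals[, , k] <- log(pmax(bp, .Machine$double.xmin))
      fnames[k] <- paste(epochs$channels[ci], names(bands)[bi], sep = "_")
    }
  }
  dimnames(vals) <- list(NULL, NULL, fnames)
  structure(list(values = vals, times = st$times,
                 bands = bands, channels = epochs$channels,
                 conditions = epochs$conditions),
            class = "feature_tensor")
}

#' @export
print.feature_tensor <- function(x, ...) {
  cat(sprintf("<feature_tensor> %d trials x %d time-points x %d features\n",
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3]))
  cat("  features:", paste(dimnames(x$values)[[3]], collapse = ", "), "\n")
  invisible(x)
}

#' Restrict a feature tensor to a subset of bands
#'
#' @param features A [extract_bandpower()] result.
#' @param bands_subset Character vector of band names (subset of
#'   `names(features$bands)`).
#' @return A `feature_tensor` with 2 channels x `length(bands_subset)`
#'   features.
#' @export
subset_bands <- function(features, bands_subset) {
  stopifnot(inherits(features, "feature_tensor"), length(bands_subset) > 0,
            all(bands_subset %in% names(features$bands)))
  if (is.null(dimnames(features$values)[[3]])) {
    stop("feature tensor has unnamed features; cannot subset by band")
  }
  keep_names <- unlist(lapply(features$channels, function(ch)
    paste(ch, names(features$bands)[names(features$bands) %in% bands_subset],
          sep = "_")))
  idx <- match(keep_names, dimnames(features$values)[[3]])
  if (anyNA(idx)) stop("feature names do not match the band/channel layout")
  out <- features
  out$values <- features$values[, , idx, drop = FALSE]
  out$bands <- features$bands[names(features$bands) %in% bands_subset]
  out
}

#' Subset a feature tensor by trial index
#' @param features A `feature_tensor`.
#' @param idx Trial indices to keep.
#' @export
subset_feature_trials <- function(features, idx) {
  out <- features
  out$values <- features$values[idx, , , drop = FALSE]
  out$conditions <- features$conditions[idx]
  out
}
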