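#' Default electrode montage
#'
#' The nine-electrode fronto-central/centro-parietal grid used for the
#' bedside assessment. Only the four non-midline electrodes (FC3, FC4,
#' CP3, CP4) feed the analysis; the rest provide context.
#' @export
smr_channels <- c("FC3", "FCz", "FC4", "C3", "Cz", "C4", "CP3", "CPz", "CP4")

#' Construct a continuous EEG recording
#'
#' @param data Numeric matrix, samples in rows, channels in columns
#'   (microvolts). Column names are the channel labels unless `channels`
#'   is given.
#' @param srate Sampling rate in Hz.
#' @param events Data frame with columns `onset_sample` (0-based: the
#'   instruction starts at time `onset_sample / srate`) and `condition`.
#' @param channels Optional character vector of channel labels.
#'
#' @return An object of class `eeg_recording`: a list with elements
#'   `data`, `srate`, `channels`, `events`.
#' @export
eeg_recording <- function(data, srate, events = NULL, channels = NULL) {
  data <- as.matrix(data)
  if (!is.null(channels)) colnames(data) <- channels
  if (is.null(colnames(data))) {
    colnames(data) <- paste0("ch", seq_len(ncol(data)))
  }
  if (is.null(events)) {
    events <- data.frame(onset_sample = integer(0),
                         condition = character(0),
                         stringsAsFactors = FALSE)
  }
  stopifnot(is.numeric(srate), srate > 0,
            all(c("onset_sample", "condition") %in% names(events)))
  if (nrow(events) > 0 &&
      (any(events$onset_sample < 0) ||
       any(events$onset_sample >= nrow(data)))) {
    stop("events fall outside the recording")
  }
  structure(list(data = data, srate = srate,
                 channels = colnames(data), events = events),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              ncol(x$data), nrow(x$data), x$srate,
              nrow(x$data) / x$srate, nrow(x$events)))
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  invisible(x)
}

n_samples <- function(rec) nrow(rec$data)
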