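#' Construct an epoched dataset
#'
#' @param data Numeric array, trials x channels x samples (microvolts).
#' @param srate Sampling rate, Hz.
#' @param conditions Character vector of per-trial condition labels.
#' @param time Time axis in seconds relative to instruction *offset*
#'   (onset at -2 s, offset at 0 s).
#' @param montage "monopolar" or "bipolar".
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, srate, conditions, time,
                       montage = c("monopolar", "bipolar")) {
  montage <- match.arg(montage)
  stopifnot(length(dim(data)) == 3,
            dim(data)[1] == length(conditions),
            dim(data)[3] == length(time))
  structure(list(data = data, srate = srate,
                 conditions = as.character(conditions),
                 time = time,
                 channels = dimnames(data)[[2]],
                 montage = montage),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %d trials x %d channels x %d samples @ %g Hz (%s)\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$srate,
              x$montage))
  print(table(x$conditions))
  invisible(x)
}

n_trials <- function(ep) dim(ep$data)[1]

#' Segment a continuous recording into instruction-locked epochs
#'
#' Cuts one 6-second epoch per event, time-locked to instruction onset
#' (half-open window `[onset, onset + 6 s)`). The time axis is relabeled
#' relative to instruction *offset*: onset at -2.0 s, offset at 0.0 s,
#' epoch end just before +4.0 s (600 samples at 100 Hz). Events too close
#' to the end of the recording are dropped with a warning.
#'
#' @param raw An [eeg_recording()] with events.
#' @param epoch_length Epoch length in seconds.
#' @param onset_to_offset Instruction duration in seconds (time-axis shift).
#' @return An [eeg_epochs()] (monopolar).
#' @export
epoch_recording <- function(raw, epoch_length = 6, onset_to_offset = 2) {
  stopifnot(inherits(raw, "eeg_recording"), nrow(raw$events) > 0)
  fs <- raw$srate
  len <- round(epoch_length * fs)
  n <- n_samples(raw)
  starts <- raw$events$onset_sample          # 0-based
  ok <- starts >= 0 & (starts + len) <= n
  if (any(!ok)) {
    warning(sum(!ok), " event(s) too close to the recording edge; dropped")
  }
  starts <- starts[ok]
  conds <- raw$events$condition[ok]
  if (length(starts) == 0) stop("no events with a full epoch of data")
  nc <- ncol(raw$data)
  data <- array(0, dim = c(length(starts), nc, len),
                dimnames = list(NULL, colnames(raw$data), NULL))
  for (i in seq_along(starts)) {
    data[i, , ] <- t(raw$data[(starts[i] + 1L):(starts[i] + len), ,
                              drop = FALSE])
  }
  time <- (0:(len - 1L)) / fs - onset_to_offset
  eeg_epochs(data, fs, conds, time, montage = "monopolar")
}

#' Bipolar derivation C3' = FC3 - CP3, C4' = FC4 - CP4
#'
#' Re-references epochs to the two fronto-central minus centro-parietal
#' bipolar channels, which emphasize local sensorimotor rhythms by
#' cancelling distal common sources: any signal common to all monopolar
#' channels (including the recording reference) vanishes exactly.
#' Channels are looked up by label, so input channel order is irrelevant.
#'
#' @param epochs A monopolar [eeg_epochs()] containing FC3, CP3, FC4, CP4.
#' @return An [eeg_epochs()] with channels `C3'` and `C4'`, montage
#'   "bipolar".
#' @export
rereference_bipolar <- function(epochs) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  need <- c("FC3", "CP3", "FC4", "CP4")
  missing <- setdiff(need, epochs$channels)
  if (length(missing) > 0) {
    stop("missing electrode(s) for bipolar derivation: ",
         paste(missing, collapse = ", "))
  }
  d <- epochs$data
  out <- array(0, dim = c(dim(d)[1], 2L, dim(d)[3]),
               dimnames = list(NULL, c("C3'", "C4'"), NULL))
  out[, 1L, ] <- d[, "FC3", ] - d[, "CP3", ]
  out[, 2L, ] <- d[, "FC4", ] - d[, "CP4", ]
  eeg_epochs(out, epochs$srate, epochs$conditions, epochs$time,
             montage = "bipolar")
}

#' Subset epochs by trial index
#' @param epochs An `eeg_epochs`.
#' @param idx Trial indices to keep.
#' @export
subset_trials <- function(epochs, idx) {
  eeg_epochs(epochs$data[idx, , , drop = FALSE], epochs$srate,
             epochs$conditions[idx], epochs$time, montage = epochs$montage)
}

#' Subsample trials to fixed per-condition counts
#'
#' Seeded random subsampling without replacement, used to equate trial
#' numbers across datasets (e.g. to the 36/33/34 left/right/rest counts
#' that survived artifact rejection in the reference bedside recording).
#' Trials keep their original temporal order.
#'
#' @param epochs An [eeg_epochs()].
#' @param target_counts Named integer vector, e.g.
#'   `c(left = 36, right = 33, rest = 34)`.
#' @param seed Integer seed.
#' @return An [eeg_epochs()] with exactly the requested counts.
#' @export
match_trial_counts <- function(epochs, target_counts, seed) {
  stopifnot(inherits(epochs, "eeg_epochs"), !is.null(names(target_counts)))
  avail <- table(epochs$conditions)
  for (cond in names(target_counts)) {
    have <- if (cond %in% names(avail)) avail[[cond]] else 0L
    if (have < target_counts[[cond]]) {
      stop(sprintf("insufficient '%s' trials: have %d, need %d (deficit %d)",
                   cond, have, target_counts[[cond]],
                   target_counts[[cond]] - have))
    }
  }
  keep <- with_seed(seed, {
    sel <- unlist(lapply(names(target_counts), function(cond) {
      idx <- which(epochs$conditions == cond)
      sample(idx, target_counts[[cond]])
    }))
    sort(sel)
  })
  subset_trials(epochs, keep)
}
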