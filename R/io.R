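# -- Recording I/O -------------------------------------------------------
#
# Two on-disk forms: a plain CSV fixture dialect (header row of channel
# labels, one row per sample, microvolts; values printed with %.17g so
# round trips are bit-identical) and 16-bit EDF. No maintained R EDF
# package is available offline, so a minimal EDF writer/reader lives
# here; it writes 1-second data records, padding the final record with
# zeros, and stores the true sample count in the reserved header field
# ("NSAMP=<n>") so the reader can trim exactly.
#
# Events travel in a sidecar TSV (<stem>.events.tsv) with columns
# onset_sample (0-based) and condition.

events_sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".events.tsv")
}

write_events_tsv <- function(events, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("onset_sample\tcondition", con)
  if (nrow(events) > 0) {
    writeLines(paste(events$onset_sample, events$condition, sep = "\t"), con)
  }
  invisible(path)
}

read_events_tsv <- function(path) {
  if (!file.exists(path)) {
    return(data.frame(onset_sample = integer(0), condition = character(0),
                      stringsAsFactors = FALSE))
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$onset_sample <- as.integer(df$onset_sample)
  df
}

#' Write a recording to disk
#'
#' @param recording An [eeg_recording()] with finite samples.
#' @param path Output file path.
#' @param format "csv" (plain-text fixture dialect, bit-exact round trip)
#'   or "edf" (16-bit European Data Format; round trip exact to one
#'   quantization step of the declared physical range). The event table is
#'   written alongside as `<stem>.events.tsv`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path, format = c("csv", "edf")) {
  format <- match.arg(format)
  stopifnot(inherits(recording, "eeg_recording"),
            all(is.finite(recording$data)))
  if (format == "csv") write_recording_csv(recording, path)
  else write_recording_edf(recording, path)
  write_events_tsv(recording$events, events_sidecar_path(path))
  invisible(path)
}

#' Read a recording from disk
#'
#' @param path File path (a `<stem>.events.tsv` sidecar is picked up
#'   automatically if present).
#' @param format "csv" or "edf".
#' @param srate Sampling rate in Hz; required for CSV (the dialect does
#'   not carry it), ignored for EDF.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, format = c("csv", "edf"), srate = NULL) {
  format <- match.arg(format)
  rec <- if (format == "csv") {
    if (is.null(srate)) stop("srate is required to read the CSV dialect")
    read_recording_csv(path, srate)
  } else {
    read_recording_edf(path)
  }
  rec$events <- read_events_tsv(events_sidecar_path(path))
  if (nrow(rec$events) > 0 &&
      any(rec$events$onset_sample >= n_samples(rec))) {
    stop("sidecar events fall outside the recording")
  }
  rec
}

write_recording_csv <- function(recording, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(recording$channels, collapse = ","), con)
  rows <- apply(recording$data, 1, function(r)
    paste(sprintf("%.17g", r), collapse = ","))
  writeLines(rows, con)
  invisible(path)
}

read_recording_csv <- function(path, srate) {
  df <- read.csv(path, check.names = FALSE)
  eeg_recording(as.matrix(df), srate)
}

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF header field too long: ", x)
  formatC(x, width = width, flag = "-")
}

write_recording_edf <- function(recording, path) {
  d <- recording$data
  fs <- recording$srate
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  fs <- as.integer(fs)
  n <- nrow(d); nc <- ncol(d)
  n_rec <- ceiling(n / fs)
  amax <- max(abs(d), 1e-6)
  phys_max <- signif(amax * 1.0001, 6)
  pm_str <- formatC(phys_max, format = "g", digits = 6)
  if (nchar(pm_str) > 7) pm_str <- formatC(phys_max, format = "e", digits = 1)
  phys_max <- as.numeric(pm_str)
  if (phys_max < amax) stop("amplitude exceeds declared physical range")
  phys_min <- -phys_max
  dig_min <- -32768L; dig_max <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(s, w) writeChar(edf_pad(s, w), con, nchars = w, eos = NULL)
  put("0", 8)
  put("X", 80)                          # patient id (anonymous fixture)
  put("Startdate X X X X", 80)
  put("01.01.01", 8); put("00.00.00", 8)
  put(as.character(256L * (nc + 1L)), 8)
  put(sprintf("NSAMP=%d", n), 44)       # true sample count (see note above)
  put(as.character(n_rec), 8)
  put("1", 8)                           # record duration, seconds
  put(as.character(nc), 4)
  for (lab in recording$channels) put(lab, 16)
  for (i in seq_len(nc)) put("simulated EEG", 80)
  for (i in seq_len(nc)) put("uV", 8)
  for (i in seq_len(nc)) put(formatC(phys_min, format = "g", digits = 6), 8)
  for (i in seq_len(nc)) put(pm_str, 8)
  for (i in seq_len(nc)) put(as.character(dig_min), 8)
  for (i in seq_len(nc)) put(as.character(dig_max), 8)
  for (i in seq_len(nc)) put("", 80)
  for (i in seq_len(nc)) put(as.character(fs), 8)
  for (i in seq_len(nc)) put("", 32)

  scale <- (dig_max - dig_min) / (phys_max - phys_min)
  dig <- round((d - phys_min) * scale) + dig_min
  dig[dig > dig_max] <- dig_max
  dig[dig < dig_min] <- dig_min
  storage.mode(dig) <- "integer"
  padded <- matrix(0L, n_rec * fs, nc)
  padded[seq_len(n), ] <- dig
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(as.vector(padded[rows, ])), con,
             size = 2L, endian = "little")
  }
  invisible(path)
}

read_recording_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  get <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  get(8); get(80); get(80); get(8); get(8)
  get(8)                                # header bytes
  reserved <- get(44)
  n_rec <- as.integer(get(8))
  rec_dur <- as.numeric(get(8))
  nc <- as.integer(get(4))
  labels <- vapply(seq_len(nc), function(i) get(16), "")
  for (i in seq_len(nc)) get(80)
  for (i in seq_len(nc)) get(8)
  phys_min <- as.numeric(vapply(seq_len(nc), function(i) get(8), ""))
  phys_max <- as.numeric(vapply(seq_len(nc), function(i) get(8), ""))
  dig_min <- as.numeric(vapply(seq_len(nc), function(i) get(8), ""))
  dig_max <- as.numeric(vapply(seq_len(nc), function(i) get(8), ""))
  for (i in seq_len(nc)) get(80)
  ns_rec <- as.integer(vapply(seq_len(nc), function(i) get(8), ""))
  for (i in seq_len(nc)) get(32)

  stopifnot(length(unique(ns_rec)) == 1L)
  fs <- ns_rec[1] / rec_dur
  total <- n_rec * ns_rec[1]
  d <- matrix(0, total, nc, dimnames = list(NULL, labels))
  for (r in seq_len(n_rec)) {
    block <- readBin(con, "integer", n = ns_rec[1] * nc, size = 2L,
                     signed = TRUE, endian = "little")
    d[((r - 1L) * ns_rec[1] + 1L):(r * ns_rec[1]), ] <-
      matrix(block, ns_rec[1], nc)
  }
  for (ci in seq_len(nc)) {
    scale <- (phys_max[ci] - phys_min[ci]) / (dig_max[ci] - dig_min[ci])
    d[, ci] <- (d[, ci] - dig_min[ci]) * scale + phys_min[ci]
  }
  if (grepl("^NSAMP=", reserved)) {
    n_true <- as.integer(sub("^NSAMP=", "", reserved))
    if (n_true >= 1 && n_true <= total) d <- d[seq_len(n_true), , drop = FALSE]
  }
  eeg_recording(d, fs)
}
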