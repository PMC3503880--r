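#' Automated artifact rejection
#'
#' Reproducible stand-in for visual artifact inspection. A trial is
#' rejected if, on any channel, (a) its peak-to-peak amplitude exceeds
#' `ptp_threshold` microvolts, or (b) the robust z-score of its
#' log-variance across trials (median/MAD per channel) exceeds
#' `var_zmax`. The robust z keeps a minority of very large artifacts from
#' masking themselves by inflating the spread estimate.
#'
#' @param epochs An [eeg_epochs()] (the defaults are tuned for the
#'   bipolar montage).
#' @param ptp_threshold Peak-to-peak rejection threshold, microvolts.
#' @param var_zmax Robust z-score threshold on per-trial log-variance.
#' @return A list with elements `epochs` (clean trials only) and `report`
#'   (class `rejection_report`: kept/rejected indices, per-condition kept
#'   counts, and the criterion parameters).
#' @export
reject_artifacts <- function(epochs, ptp_threshold = 150, var_zmax = 5) {
  stopifnot(inherits(epochs, "eeg_epochs"),
            ptp_threshold > 0, var_zmax > 0)
  d <- epochs$data
  nt <- dim(d)[1]; nc <- dim(d)[2]
  ptp <- matrix(0, nt, nc)
  v <- matrix(0, nt, nc)
  for (ci in seq_len(nc)) {
    m <- d[, ci, , drop = TRUE]
    if (nt == 1L) m <- matrix(m, nrow = 1L)
    ptp[, ci] <- apply(m, 1, function(x) max(x) - min(x))
    v[, ci] <- apply(m, 1, stats::var)
  }
  logv <- log(pmax(v, .Machine$double.xmin))
  z <- matrix(0, nt, nc)
  for (ci in seq_len(nc)) {
    med <- median(logv[, ci])
    s <- mad(logv[, ci])
    z[, ci] <- if (s > 0) (logv[, ci] - med) / s else 0
  }
  bad <- apply(ptp > ptp_threshold, 1, any) | apply(z > var_zmax, 1, any)
  if (all(bad)) stop("all trials rejected; pipeline cannot proceed")
  kept <- which(!bad)
  rejected <- which(bad)
  report <- structure(list(
    kept = kept,
    rejected = rejected,
    kept_by_condition = table(factor(epochs$conditions[kept],
                                     levels = unique(epochs$conditions))),
    rejected_by_condition = table(factor(epochs$conditions[rejected],
                                         levels = unique(epochs$conditions))),
    params = list(ptp_threshold = ptp_threshold, var_zmax = var_zmax,
                  criterion = "peak-to-peak OR robust log-variance z")
  ), class = "rejection_report")
  list(epochs = subset_trials(epochs, kept), report = report)
}

#' @export
print.rejection_report <- function(x, ...) {
  cat(sprintf("<rejection_report> kept %d / %d trials (ptp > %g uV or log-var z > %g)\n",
              length(x$kept), length(x$kept) + length(x$rejected),
              x$params$ptp_threshold, x$params$var_zmax))
  cat("  kept by condition:\n")
  print(x$kept_by_condition)
  invisible(x)
}
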