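# Base-graphics visualizations analogous to the usual bedside-assessment
# figures: log power-ratio maps with significant clusters outlined, and
# accuracy timecourses with significance stars.

#' Plot a time-frequency contrast with significant clusters highlighted
#'
#' @param contrast Array channels x freqs x times from
#'   [contrast_log_ratio()].
#' @param tfr The `eeg_tfr` the contrast came from (axes).
#' @param clusters Optional `cluster_result`; significant clusters are
#'   overlaid as points.
#' @param channel Channel label to plot.
#' @export
plot_contrast <- function(contrast, tfr, clusters = NULL,
                          channel = dimnames(contrast)[[1]][1]) {
  ci <- match(channel, dimnames(contrast)[[1]])
  z <- t(contrast[ci, , ])
  lim <- max(abs(z))
  cols <- grDevices::hcl.colors(65, "Blue-Red 3")
  graphics::image(tfr$times, tfr$freqs, z, zlim = c(-lim, lim), col = cols,
                  xlab = "Time from instruction offset (s)",
                  ylab = "Frequency (Hz)",
                  main = sprintf("%s: log power ratio vs rest", channel))
  graphics::abline(v = 0, lty = 2)
  if (!is.null(clusters)) {
    for (cl in clusters$channels[[channel]]$clusters) {
      if (!cl$significant) next
      graphics::points(cl$cells$time, cl$cells$freq, pch = 0, cex = 0.6)
    }
  }
  invisible(NULL)
}

#' Plot an accuracy timecourse with significance stars
#'
#' @param x A `fw_perm_result` (or `accuracy_timecourse`).
#' @param ... Passed to `plot`.
#' @export
plot.fw_perm_result <- function(x, ...) {
  obs <- x$observed
  graphics::plot(obs$times, 100 * obs$smoothed, type = "l", lwd = 2,
                 ylim = c(30, 100),
                 xlab = "Time from instruction offset (s)",
                 ylab = "Smoothed accuracy (%)", ...)
  se <- apply(x$observed$fold_acc, 2, stats::sd) / sqrt(x$observed$k)
  sm_se <- smooth_timecourse(se)
  graphics::polygon(c(obs$times, rev(obs$times)),
                    100 * c(obs$smoothed + sm_se, rev(obs$smoothed - sm_se)),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::abline(h = 50, lty = 2)
  if (any(x$significant)) {
    graphics::points(obs$times[x$significant],
                     100 * obs$smoothed[x$significant] + 3, pch = 8)
  }
  invisible(x)
}

#' @export
plot.accuracy_timecourse <- function(x, ...) {
  graphics::plot(x$times, 100 * x$smoothed, type = "l", lwd = 2,
                 ylim = c(30, 100),
                 xlab = "Time from instruction offset (s)",
                 ylab = "Smoothed accuracy (%)", ...)
  graphics::lines(x$times, 100 * x$raw, col = "grey60")
  graphics::abline(h = 50, lty = 2)
  invisible(x)
}

#' Plot Welch spectra per condition (clinical-style average spectrum)
#'
#' @param spectra Named list of `welch_spectrum` objects (one per
#'   condition).
#' @param channel Channel label.
#' @param fmax Upper frequency limit for the plot, Hz.
#' @export
plot_welch <- function(spectra, channel = spectra[[1]]$channels[1],
                       fmax = 40) {
  cols <- seq_along(spectra)
  first <- TRUE
  for (i in seq_along(spectra)) {
    w <- spectra[[i]]
    ci <- match(channel, w$channels)
    sel <- w$freqs <= fmax & w$freqs > 0
    if (first) {
      graphics::plot(w$freqs[sel], w$power_db[ci, sel], type = "l",
                     col = cols[i], lwd = 2, xlab = "Frequency (Hz)",
                     ylab = "Power (dB)",
                     main = sprintf("%s average spectrum", channel))
      first <- FALSE
    } else {
      graphics::lines(w$freqs[sel], w$power_db[ci, sel], col = cols[i],
                      lwd = 2)
    }
  }
  graphics::legend("topright", legend = names(spectra), col = cols, lwd = 2,
                   bty = "n")
  invisible(NULL)
}

write_report_figures <- function(stage_objects, out_dir) {
  so <- stage_objects
  for (cond in c("left", "right")) {
    fw <- so[[paste0("classification_", cond)]]
    if (is.null(fw)) next
    grDevices::png(file.path(out_dir, paste0("accuracy_", cond, ".png")),
                   width = 800, height = 500)
    plot(fw, main = paste(cond, "vs rest"))
    grDevices::dev.off()
    clus <- so[[paste0("clusters_", cond)]]
    idx_a <- which(so$tfr$conditions == cond)
    idx_r <- which(so$tfr$conditions == "rest")
    lr <- contrast_log_ratio(subset_tfr_trials(so$tfr, idx_a),
                             subset_tfr_trials(so$tfr, idx_r))
    for (ch in dimnames(lr)[[1]]) {
      fname <- sprintf("tfr_%s_%s.png", cond, gsub("'", "p", ch))
      grDevices::png(file.path(out_dir, fname), width = 800, height = 500)
      plot_contrast(lr, so$tfr, clus, channel = ch)
      grDevices::dev.off()
    }
  }
  invisible(NULL)
}
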