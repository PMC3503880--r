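# -- Cluster-based permutation testing on time-frequency maps -----------

# Connected components of a logical freq x time matrix under
# 4-adjacency (+-1 frequency bin, +-1 time cell, no diagonals).
# Returns a list of integer cell-index vectors (column-major).
grid_components <- function(mask) {
  nf <- nrow(mask); ntm <- ncol(mask)
  lab <- matrix(0L, nf, ntm)
  comps <- list()
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    head <- 1L
    while (head <= length(queue)) {
      cell <- queue[head]; head <- head + 1L
      f <- (cell - 1L) %% nf + 1L
      tt <- (cell - 1L) %/% nf + 1L
      nbrs <- c(if (f > 1L) cell - 1L,
                if (f < nf) cell + 1L,
                if (tt > 1L) cell - nf,
                if (tt < ntm) cell + nf)
      for (nb in nbrs) {
        if (mask[nb] && lab[nb] == 0L) {
          lab[nb] <- cur
          queue <- c(queue, nb)
        }
      }
    }
    comps[[cur]] <- queue
  }
  comps
}

# Pooled-variance independent-samples t for every column of X, where
# rows i1 form group 1 and the rest group 2. S/SS are colSums of X/X^2.
tstat_cols <- function(X, X2, i1, S, SS) {
  n <- nrow(X); n1 <- length(i1); n2 <- n - n1
  s1 <- colSums(X[i1, , drop = FALSE])
  ss1 <- colSums(X2[i1, , drop = FALSE])
  m1 <- s1 / n1; m2 <- (S - s1) / n2
  sp2 <- (ss1 - n1 * m1^2 + (SS - ss1) - n2 * m2^2) / (n1 + n2 - 2)
  sp2[sp2 < 0] <- 0
  tt <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  tt
}

# Max |cluster sum| of supra-threshold t-cells (both signs), 0 if none.
max_cluster_sum <- function(tt, tcrit, nf, ntm) {
  best <- 0
  for (sgn in c(1, -1)) {
    mask <- matrix(sgn * tt > tcrit & is.finite(tt), nf, ntm)
    if (!any(mask)) next
    for (cells in grid_components(mask)) {
      s <- abs(sum(tt[cells]))
      if (s > best) best <- s
    }
  }
  best
}

cluster_perm_channel <- function(A, B, sample_alpha, n_perm, cluster_alpha,
                                 freqs, times) {
  nf <- length(freqs); ntm <- length(times)
  Am <- matrix(A, dim(A)[1], nf * ntm)
  Bm <- matrix(B, dim(B)[1], nf * ntm)
  X <- rbind(Am, Bm)
  X2 <- X * X
  n1 <- nrow(Am); n2 <- nrow(Bm); n <- n1 + n2
  S <- colSums(X); SS <- colSums(X2)
  df <- n - 2
  tcrit <- qt(1 - sample_alpha / 2, df)

  t_obs <- tstat_cols(X, X2, seq_len(n1), S, SS)
  excluded <- which(!is.finite(t_obs))
  if (length(excluded) > 0) {
    warning(length(excluded),
            " cell(s) with zero variance across all trials excluded")
    t_obs[excluded] <- NA_real_
  }

  clusters <- list()
  for (sgn in c(1, -1)) {
    mask <- matrix(!is.na(t_obs) & sgn * t_obs > tcrit, nf, ntm)
    for (cells in grid_components(mask)) {
      fi <- (cells - 1L) %% nf + 1L
      ti <- (cells - 1L) %/% nf + 1L
      clusters[[length(clusters) + 1L]] <- list(
        sign = if (sgn > 0) "+" else "-",
        stat = sum(t_obs[cells]),
        cells = data.frame(freq = freqs[fi], time = times[ti]))
    }
  }

  null <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    i1 <- sample.int(n, n1)
    tp <- tstat_cols(X, X2, i1, S, SS)
    tp[!is.finite(tp)] <- 0
    null[p] <- max_cluster_sum(tp, tcrit, nf, ntm)
  }

  for (k in seq_along(clusters)) {
    pval <- (1 + sum(null >= abs(clusters[[k]]$stat))) / (1 + n_perm)
    clusters[[k]]$p <- pval
    clusters[[k]]$significant <- pval < cluster_alpha
  }
  list(clusters = clusters, null = null, excluded_cells = excluded,
       t_threshold = tcrit)
}

#' Cluster-based permutation test between two trial sets
#'
#' Nonparametric contrast of per-trial time-frequency power between two
#' conditions, run separately per channel. Every (frequency, time) cell
#' is compared with a pooled-variance independent-samples t-test; cells
#' significant at `sample_alpha` (two-tailed) are clustered by 4-adjacency
#' in the time-frequency plane separately by sign, and each cluster's
#' statistic is the sum of its t-values (no size limits). Significance is
#' Monte Carlo: trials are randomly re-partitioned into groups of the
#' original sizes `n_perm` times, the maximum absolute cluster sum per
#' partition forms the null distribution, and each observed cluster gets
#' `p = (1 + #(null >= |sum|)) / (1 + n_perm)`, flagged significant when
#' `p < cluster_alpha` (default .05/4: two comparisons x two channels).
#'
#' @param tfr_a,tfr_b `eeg_tfr` objects with matching axes (or plain 3-d
#'   arrays trials x freqs x times, treated as a single channel).
#' @param sample_alpha Cell-level threshold (two-tailed).
#' @param n_perm Number of random partitions.
#' @param cluster_alpha Cluster-level significance threshold.
#' @param seed Integer seed for the random partitions.
#' @return Object of class `cluster_result`: per-channel cluster lists
#'   (cells, sign, t-sum, Monte Carlo p, significance), the null
#'   distributions, and the thresholds used.
#' @export
cluster_permutation_test <- function(tfr_a, tfr_b, sample_alpha = 0.05,
                                     n_perm = 1000, cluster_alpha = 0.0125,
                                     seed = 1) {
  if (is.array(tfr_a) && length(dim(tfr_a)) == 3) {
    stopifnot(is.array(tfr_b), identical(dim(tfr_a)[-1], dim(tfr_b)[-1]))
    nf <- dim(tfr_a)[2]; ntm <- dim(tfr_a)[3]
    tfr_a <- list(power = array(tfr_a, c(dim(tfr_a)[1], 1, nf, ntm)),
                  freqs = seq_len(nf), times = seq_len(ntm),
                  channels = "ch1")
    class(tfr_a) <- "eeg_tfr"
    tfr_b <- list(power = array(tfr_b, c(dim(tfr_b)[1], 1, nf, ntm)),
                  freqs = tfr_a$freqs, times = tfr_a$times,
                  channels = "ch1")
    class(tfr_b) <- "eeg_tfr"
  }
  stopifnot(inherits(tfr_a, "eeg_tfr"), inherits(tfr_b, "eeg_tfr"),
            identical(tfr_a$freqs, tfr_b$freqs),
            identical(tfr_a$times, tfr_b$times),
            identical(tfr_a$channels, tfr_b$channels),
            dim(tfr_a$power)[1] >= 2, dim(tfr_b$power)[1] >= 2)
  channels <- tfr_a$channels
  res <- with_seed(seed, {
    lapply(seq_along(channels), function(ci) {
      cluster_perm_channel(tfr_a$power[, ci, , , drop = FALSE],
                           tfr_b$power[, ci, , , drop = FALSE],
                           sample_alpha, n_perm, cluster_alpha,
                           tfr_a$freqs, tfr_a$times)
    })
  })
  names(res) <- channels
  structure(list(channels = res,
                 freqs = tfr_a$freqs, times = tfr_a$times,
                 params = list(sample_alpha = sample_alpha,
                               n_perm = n_perm,
                               cluster_alpha = cluster_alpha,
                               adjacency = "4-connectivity",
                               seed = seed)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d channel(s), %d permutations, cluster alpha %g\n",
              length(x$channels), x$params$n_perm, x$params$cluster_alpha))
  for (ch in names(x$channels)) {
    cl <- x$channels[[ch]]$clusters
    sig <- sum(vapply(cl, function(c) c$significant, TRUE))
    cat(sprintf("  %s: %d cluster(s), %d significant\n", ch, length(cl), sig))
    for (c in cl) {
      if (!c$significant) next
      cat(sprintf("    %s cluster: %g-%g Hz x %.2f-%.2f s, sum(t)=%.1f, p=%.4f\n",
                  c$sign, min(c$cells$freq), max(c$cells$freq),
                  min(c$cells$time), max(c$cells$time), c$stat, c$p))
    }
  }
  invisible(x)
}

# Convenience: data.frame summary of all clusters.
#' Summarize clusters as a data.frame
#' @param object A `cluster_result`.
#' @param ... Unused.
#' @export
summary.cluster_result <- function(object, ...) {
  rows <- list()
  for (ch in names(object$channels)) {
    for (c in object$channels[[ch]]$clusters) {
      rows[[length(rows) + 1L]] <- data.frame(
        channel = ch, sign = c$sign,
        f_min = min(c$cells$freq), f_max = max(c$cells$freq),
        t_min = min(c$cells$time), t_max = max(c$cells$time),
        stat = c$stat, p = c$p, significant = c$significant)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(channel = character(0), sign = character(0),
                      f_min = numeric(0), f_max = numeric(0),
                      t_min = numeric(0), t_max = numeric(0),
                      stat = numeric(0), p = numeric(0),
                      significant = logical(0)))
  }
  do.call(rbind, rows)
}
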