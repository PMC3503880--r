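# -- Cross-validated accuracy timecourses --------------------------------

#' Centered moving-average smoothing with shrinking edge windows
#'
#' 500 ms at 50 ms steps = 11 points; at the edges the window shrinks to
#' the available points, so a constant sequence is unchanged and the
#' smoothed values never leave `[min(x), max(x)]`.
#'
#' @param x Numeric vector.
#' @param width Window width in points (odd).
#' @return Smoothed vector, same length.
#' @export
smooth_timecourse <- function(x, width = 11L) {
  stopifnot(width %% 2 == 1)
  hw <- (width - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - hw):min(n, i + hw)])
  }, 0)
}

# Stratified, seeded fold assignment. Each class's trials are shuffled
# and dealt round-robin into k folds; redraws (logged via warning) if any
# fold ends up with a single class, which can only happen when a class
# has fewer members than folds.
make_stratified_folds <- function(labels, k, max_tries = 100L) {
  n <- length(labels)
  classes <- unique(labels)
  for (try in seq_len(max_tries)) {
    folds <- integer(n)
    offset <- sample.int(k, 1L) - 1L
    for (cl in classes) {
      idx <- which(labels == cl)
      folds[sample(idx)] <- (seq_along(idx) + offset - 1L) %% k + 1L
    }
    ok <- all(vapply(seq_len(k), function(f) {
      length(unique(labels[folds == f])) == length(classes) ||
        sum(folds == f) == 0
    }, TRUE)) && all(tabulate(folds, k) > 0)
    if (ok) return(folds)
    warning("fold with a single class; redrawing folds")
  }
  stop("could not build stratified folds with both classes per fold")
}

# Shared validation + label encoding for the classification entry points.
prep_classification <- function(features, labels, k) {
  stopifnot(inherits(features, "feature_tensor"))
  labels <- as.character(labels)
  n <- dim(features$values)[1]
  stopifnot(length(labels) == n, n >= k)
  classes <- unique(labels)
  if (length(classes) != 2) stop("exactly two classes required")
  tie_class <- if ("rest" %in% classes) "rest" else classes[1]
  lab01 <- as.integer(labels != tie_class)   # 0 = tie/rest class
  list(labels = labels, lab01 = lab01, classes = classes,
       tie_class = tie_class, n = n,
       dims = as.integer(dim(features$values)))
}

#' Cross-validated single-trial classification accuracy
#'
#' At each time-point independently, a Gaussian naive Bayes classifier is
#' trained and tested under seeded stratified k-fold cross-validation
#' (each trial tested exactly once); the per-time-point accuracy is the
#' mean of the k fold accuracies, and a 500 ms (11-point) centered moving
#' average gives the smoothed timecourse.
#'
#' @param features A [extract_bandpower()] tensor.
#' @param labels Per-trial class labels (2 classes, e.g. "left"/"rest").
#' @param k Number of folds.
#' @param seed Integer seed (fold assignment).
#' @param smooth_width Smoothing window in points.
#' @return Object of class `accuracy_timecourse`: `raw`, `smoothed`,
#'   `fold_acc` (k x time), `times` (s), `folds`, `n_per_class`.
#' @export
crossval_accuracy <- function(features, labels, k = 10L, seed = 1,
                              smooth_width = 11L) {
  pc <- prep_classification(features, labels, k)
  folds <- with_seed(seed, make_stratified_folds(pc$labels, k))
  fold_acc <- cpp_cv_fold_accuracy(as.numeric(features$values), pc$dims,
                                   pc$lab01, folds, as.integer(k))
  raw <- colMeans(fold_acc)
  structure(list(raw = raw,
                 smoothed = smooth_timecourse(raw, smooth_width),
                 fold_acc = fold_acc,
                 times = features$times,
                 folds = folds,
                 k = as.integer(k),
                 n_per_class = table(pc$labels),
                 classes = pc$classes,
                 seed = seed),
            class = "accuracy_timecourse")
}

#' @export
print.accuracy_timecourse <- function(x, ...) {
  i <- which.max(x$smoothed)
  cat(sprintf("<accuracy_timecourse> %d time-points, %d-fold CV (%s)\n",
              length(x$raw), x$k,
              paste(sprintf("%s=%d", names(x$n_per_class), x$n_per_class),
                    collapse = ", ")))
  cat(sprintf("  max smoothed %.1f%% at %+.0f ms (max raw %.1f%% at %+.0f ms)\n",
              100 * x$smoothed[i], 1000 * x$times[i],
              100 * max(x$raw), 1000 * x$times[which.max(x$raw)]))
  invisible(x)
}

#' Familywise max-statistic randomization test of classification accuracy
#'
#' Assesses the cross-validated accuracy timecourse against chance while
#' jointly controlling the familywise error over time-points: at each of
#' `n_perm` permutations the class labels are shuffled, the full
#' cross-validated classification (with freshly drawn stratified folds)
#' is repeated, and the best smoothed accuracy across time-points is
#' recorded. `p(t) = (1 + #(null max >= smoothed(t))) / (1 + n_perm)`;
#' time-points with `p < alpha` (default .05/2, one-tailed, for the two
#' hand-vs-rest comparisons) are flagged significant.
#'
#' @inheritParams crossval_accuracy
#' @param n_perm Number of label permutations (a warning is issued below
#'   100; the null tail is unstable there).
#' @param alpha One-tailed significance threshold.
#' @return Object of class `fw_perm_result`: the observed
#'   `accuracy_timecourse`, `null` (max smoothed accuracy per
#'   permutation), `p` per time-point, logical `significant` mask,
#'   `max_accuracy` and `max_time` (s).
#' @export
familywise_permutation_test <- function(features, labels, k = 10L,
                                        n_perm = 1000L, alpha = 0.025,
                                        seed = 1, smooth_width = 11L) {
  pc <- prep_classification(features, labels, k)
  if (n_perm < 100) warning("n_perm < 100: permutation tail is unstable")
  observed <- crossval_accuracy(features, labels, k = k, seed = seed,
                                smooth_width = smooth_width)
  n <- pc$n
  perms <- with_seed(seed + 1L, {
    lab_mat <- matrix(0L, n_perm, n)
    fold_mat <- matrix(0L, n_perm, n)
    for (i in seq_len(n_perm)) {
      shuffled <- sample(pc$labels)
      lab_mat[i, ] <- as.integer(shuffled != pc$tie_class)
      fold_mat[i, ] <- make_stratified_folds(shuffled, k)
    }
    list(lab = lab_mat, fold = fold_mat)
  })
  null <- cpp_cv_perm_max(as.numeric(features$values), pc$dims,
                          perms$lab, perms$fold, as.integer(k),
                          as.integer((smooth_width - 1) / 2))
  p <- vapply(observed$smoothed, function(a)
    (1 + sum(null >= a)) / (1 + n_perm), 0)
  i <- which.max(observed$smoothed)
  structure(list(observed = observed, null = null, p = p,
                 significant = p < alpha,
                 alpha = alpha, n_perm = as.integer(n_perm),
                 max_accuracy = observed$smoothed[i],
                 max_time = observed$times[i],
                 seed = seed),
            class = "fw_perm_result")
}

#' @export
print.fw_perm_result <- function(x, ...) {
  cat(sprintf("<fw_perm_result> %d permutations, alpha %g (one-tailed)\n",
              x$n_perm, x$alpha))
  cat(sprintf("  max smoothed accuracy %.1f%% at %+.0f ms; %d significant time-point(s), min p = %.4f\n",
              100 * x$max_accuracy, 1000 * x$max_time,
              sum(x$significant), min(x$p)))
  invisible(x)
}

#' Band-restricted single-trial classification
#'
#' Runs the identical cross-validation and familywise randomization
#' pipeline on a subset of the four frequency bands (e.g. high-beta only,
#' as in a post hoc analysis restricted to the band carrying a
#' significant ERS).
#'
#' @inheritParams familywise_permutation_test
#' @param bands_subset Non-empty character vector of band names.
#' @return List with `accuracy` ([crossval_accuracy()] result) and
#'   `test` ([familywise_permutation_test()] result).
#' @export
band_restricted_classification <- function(features, labels, bands_subset,
                                           k = 10L, n_perm = 1000L,
                                           alpha = 0.025, seed = 1) {
  feats <- subset_bands(features, bands_subset)
  list(accuracy = crossval_accuracy(feats, labels, k = k, seed = seed),
       test = familywise_permutation_test(feats, labels, k = k,
                                          n_perm = n_perm, alpha = alpha,
                                          seed = seed))
}
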