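# -- Gaussian naive Bayes -----------------------------------------------
#
# Two-class Gaussian naive Bayes: per class and feature, a sample mean
# and (unbiased) standard deviation; priors from class frequencies.
# Standard deviations are floored at eps * pooled within-class SD
# (eps = 1e-6) plus a tiny absolute floor so degenerate densities cannot
# arise. Prediction is in the log domain; ties go to the designated
# tie-break class ("rest" when present) — conservative for awareness
# claims.

NB_SD_EPS <- 1e-6

#' Fit a Gaussian naive Bayes model at one time-point
#'
#' @param x Numeric matrix, trials x features.
#' @param labels Per-trial class labels (exactly 2 classes, each with
#'   >= 2 trials).
#' @param tie_break Class predicted on exact posterior ties; defaults to
#'   "rest" if present, else the first class.
#' @return Object of class `gnb_model` with per-class `means`, `sds`
#'   (floored) and `log_priors`.
#' @export
nb_fit <- function(x, labels, tie_break = NULL) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) != 2) stop("exactly two classes required, got ",
                                 length(classes))
  counts <- table(factor(labels, levels = classes))
  if (any(counts < 2)) stop("each class needs >= 2 trials")
  if (is.null(tie_break)) {
    tie_break <- if ("rest" %in% classes) "rest" else classes[1]
  }
  p <- ncol(x)
  means <- sds <- matrix(0, 2, p, dimnames = list(classes, colnames(x)))
  for (k in 1:2) {
    xi <- x[labels == classes[k], , drop = FALSE]
    means[k, ] <- colMeans(xi)
    sds[k, ] <- apply(xi, 2, stats::sd)
  }
  pooled <- sqrt(((counts[1] - 1) * sds[1, ]^2 +
                    (counts[2] - 1) * sds[2, ]^2) / (sum(counts) - 2))
  floorv <- pmax(NB_SD_EPS * pooled, .Machine$double.eps)
  sds <- pmax(sds, rep(floorv, each = 2))
  structure(list(classes = classes,
                 means = means, sds = sds,
                 log_priors = log(as.numeric(counts) / sum(counts)),
                 tie_break = tie_break),
            class = "gnb_model")
}

#' Predict with a Gaussian naive Bayes model
#'
#' Log-domain product of per-feature normal densities times the class
#' prior; the test point is assigned the class with the highest
#' posterior, ties broken toward the model's tie-break class.
#'
#' @param model A [nb_fit()] model.
#' @param x Feature vector, or matrix with one row per test point.
#' @return For a vector: list with `class` and `posterior` (named,
#'   sums to 1). For a matrix: data.frame of classes plus a posterior
#'   matrix attribute-free, one row per point.
#' @export
nb_predict <- function(model, x) {
  stopifnot(inherits(model, "gnb_model"))
  single <- is.null(dim(x))
  x <- rbind(x)
  if (any(!is.finite(x))) stop("non-finite feature value")
  n <- nrow(x)
  ll <- matrix(0, n, 2)
  for (k in 1:2) {
    z <- sweep(x, 2, model$means[k, ]) / rep(model$sds[k, ], each = n)
    ll[, k] <- model$log_priors[k] +
      rowSums(-log(rep(model$sds[k, ], each = n)) - 0.5 * z^2)
  }
  post <- exp(ll - apply(ll, 1, max))
  post <- post / rowSums(post)
  colnames(post) <- model$classes
  tie_k <- match(model$tie_break, model$classes)
  other_k <- 3L - tie_k
  cls <- ifelse(ll[, other_k] > ll[, tie_k],
                model$classes[other_k], model$classes[tie_k])
  if (single) list(class = cls[1], posterior = post[1, ])
  else data.frame(class = cls, posterior = post)
}
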