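// Hot loop of the single-trial analysis: cross-validated Gaussian naive
// Bayes accuracy per time-point, and its label-permutation driver. The
// semantics mirror nb_fit()/nb_predict() in R exactly (unbiased SDs,
// SD floor of 1e-6 x pooled within-class SD with an absolute epsilon
// floor, class priors from training frequencies, ties predicted as the
// tie-break class, encoded as label 0).

#include <Rcpp.h>
#include <cmath>
#include <cfloat>
using namespace Rcpp;

// feat: n x T x P array (R dim order). labels: 0 (rest / tie-break
// class) or 1. folds: 1..k. Returns k x T matrix of fold accuracies.
static void fold_accuracy(const double* feat, int n, int T, int P,
                          const int* labels, const int* folds, int k,
                          double* acc /* k x T, preallocated */) {
  std::vector<double> m0(T * P), m1(T * P), s0(T * P), s1(T * P);
  for (int f = 1; f <= k; ++f) {
    int n0 = 0, n1 = 0, ntest = 0;
    for (int i = 0; i < n; ++i) {
      if (folds[i] == f) { ++ntest; continue; }
      if (labels[i] == 0) ++n0; else ++n1;
    }
    if (n0 < 2 || n1 < 2 || ntest == 0)
      stop("degenerate fold: need >= 2 training trials per class");
    double lp0 = std::log((double)n0 / (n0 + n1));
    double lp1 = std::log((double)n1 / (n0 + n1));

    // per-(t,p) training means and SDs per class
    for (int p = 0; p < P; ++p) {
      for (int t = 0; t < T; ++t) {
        const double* col = feat + (size_t)n * (t + (size_t)T * p);
        double sum0 = 0, sum1 = 0;
        for (int i = 0; i < n; ++i) {
          if (folds[i] == f) continue;
          if (labels[i] == 0) sum0 += col[i]; else sum1 += col[i];
        }
        double mu0 = sum0 / n0, mu1 = sum1 / n1;
        double ss0 = 0, ss1 = 0;
        for (int i = 0; i < n; ++i) {
          if (folds[i] == f) continue;
          double d = col[i] - (labels[i] == 0 ? mu0 : mu1);
          if (labels[i] == 0) ss0 += d * d; else ss1 += d * d;
        }
        double v0 = ss0 / (n0 - 1), v1 = ss1 / (n1 - 1);
        double pooled = std::sqrt(((n0 - 1) * v0 + (n1 - 1) * v1)
                                    / (n0 + n1 - 2));
        double floorv = std::max(1e-6 * pooled, DBL_EPSILON);
        int idx = t + T * p;
        m0[idx] = mu0; m1[idx] = mu1;
        s0[idx] = std::max(std::sqrt(v0), floorv);
        s1[idx] = std::max(std::sqrt(v1), floorv);
      }
    }

    // classify held-out trials at each time-point
    for (int t = 0; t < T; ++t) {
      int ncorrect = 0;
      for (int i = 0; i < n; ++i) {
        if (folds[i] != f) continue;
        double ll0 = lp0, ll1 = lp1;
        for (int p = 0; p < P; ++p) {
          int idx = t + T * p;
          double x = feat[i + (size_t)n * idx];
          double z0 = (x - m0[idx]) / s0[idx];
          double z1 = (x - m1[idx]) / s1[idx];
          ll0 += -std::log(s0[idx]) - 0.5 * z0 * z0;
          ll1 += -std::log(s1[idx]) - 0.5 * z1 * z1;
        }
        int pred = (ll1 > ll0) ? 1 : 0;   // tie -> class 0 (rest)
        if (pred == labels[i]) ++ncorrect;
      }
      acc[(f - 1) + (size_t)k * t] = (double)ncorrect / ntest;
    }
  }
}

// Centered moving average with shrinking windows at the edges.
static void smooth_ma(const double* x, int T, int halfwidth, double* y) {
  for (int t = 0; t < T; ++t) {
    int lo = std::max(0, t - halfwidth), hi = std::min(T - 1, t + halfwidth);
    double s = 0;
    for (int j = lo; j <= hi; ++j) s += x[j];
    y[t] = s / (hi - lo + 1);
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_cv_fold_accuracy(NumericVector feat, IntegerVector dims,
                                   IntegerVector labels, IntegerVector folds,
                                   int k) {
  int n = dims[0], T = dims[1], P = dims[2];
  NumericMatrix acc(k, T);
  fold_accuracy(REAL(feat), n, T, P, INTEGER(labels), INTEGER(folds), k,
                REAL(acc));
  return acc;
}

// One max-of-smoothed-accuracy statistic per permutation. labels_mat and
// folds_mat are n_perm x n (row = one permutation's shuffled labels and
// its stratified fold assignment).
// [[Rcpp::export]]
NumericVector cpp_cv_perm_max(NumericVector feat, IntegerVector dims,
                              IntegerMatrix labels_mat,
                              IntegerMatrix folds_mat,
                              int k, int halfwidth) {
  int n = dims[0], T = dims[1], P = dims[2];
  int n_perm = labels_mat.nrow();
  NumericVector out(n_perm);
  std::vector<double> acc((size_t)k * T), raw(T), sm(T);
  std::vector<int> lab(n), fol(n);
  for (int pi = 0; pi < n_perm; ++pi) {
    for (int i = 0; i < n; ++i) {
      lab[i] = labels_mat(pi, i);
      fol[i] = folds_mat(pi, i);
    }
    fold_accuracy(REAL(feat), n, T, P, lab.data(), fol.data(), k,
                  acc.data());
    for (int t = 0; t < T; ++t) {
      double s = 0;
      for (int f = 0; f < k; ++f) s += acc[f + (size_t)k * t];
      raw[t] = s / k;
    }
    smooth_ma(raw.data(), T, halfwidth, sm.data());
    double best = 0;
    for (int t = 0; t < T; ++t) if (sm[t] > best) best = sm[t];
    out[pi] = best;
    if (pi % 50 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
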