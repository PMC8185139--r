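#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Template-match counting shared by approximate and sample entropy.
//
// One pass over ordered pairs (i, j), i < j, computing the Chebyshev
// distance between the length-m templates starting at i and j and, where
// both indices admit it, the length-(m+1) extension.  Returns everything
// the two estimators need:
//   - per-template inclusive match counts for ApEn (self-match included),
//     at dimensions m and m+1;
//   - pair match totals A (dimension m+1) and B (dimension m) for SampEn,
//     restricted to the first N - m templates as is standard.
//
// The hot path is the default embedding m = 2, which gets a hand-unrolled
// loop; other m fall back to the generic loop.
// [[Rcpp::export]]
List entropy_match_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  if (n <= m + 1) stop("series too short: need length > m + 1");
  if (r < 0) stop("tolerance r must be non-negative");

  const int n_m  = n - m + 1;  // number of m-templates
  const int n_m1 = n - m;      // number of (m+1)-templates

  IntegerVector cm(n_m, 1);    // ApEn counts, self-match included
  IntegerVector cm1(n_m1, 1);
  double A = 0.0, B = 0.0;
  const double *xv = REAL(x);
  int *cmv = INTEGER(cm), *cm1v = INTEGER(cm1);

  if (m == 2) {
    for (int i = 0; i < n_m; ++i) {
      const double xi0 = xv[i], xi1 = xv[i + 1], xi2 = xv[i + 2];
      for (int j = i + 1; j < n_m; ++j) {
        double d0 = std::fabs(xi0 - xv[j]);
        double d1 = std::fabs(xi1 - xv[j + 1]);
        if (d0 <= r && d1 <= r) {
          cmv[i] += 1; cmv[j] += 1;
          if (j < n_m1) {
            B += 1.0;
            if (std::fabs(xi2 - xv[j + 2]) <= r) {
              cm1v[i] += 1; cm1v[j] += 1;
              A += 1.0;
            }
          }
        }
      }
    }
  } else {
    for (int i = 0; i < n_m; ++i) {
      for (int j = i + 1; j < n_m; ++j) {
        double d = 0.0;
        for (int k = 0; k < m; ++k) {
          double dk = std::fabs(xv[i + k] - xv[j + k]);
          if (dk > d) d = dk;
          if (d > r) break;
        }
        if (d <= r) {
          cmv[i] += 1; cmv[j] += 1;
          if (j < n_m1) {
            B += 1.0;
            if (std::max(d, std::fabs(xv[i + m] - xv[j + m])) <= r) {
              cm1v[i] += 1; cm1v[j] += 1;
              A += 1.0;
            }
          }
        }
      }
    }
  }

  return List::create(_["cm"] = cm, _["cm1"] = cm1,
                      _["A"] = A, _["B"] = B,
                      _["n_m"] = n_m, _["n_m1"] = n_m1);
}
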