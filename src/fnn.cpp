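#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// False-nearest-neighbor fractions for one embedding dimension d.
//
// Usable points i = 0..M-1 with M = N - d*tau: each has the d-dimensional
// delay vector (x[i], x[i+tau], ..., x[i+(d-1)tau]) and the extension
// coordinate x[i+d*tau].  The nearest neighbor is searched in dimension d
// (Euclidean metric) among the same M points, excluding |i-j| <= theiler;
// distance ties break to the smallest index.
//
// Test 1 (ratio test):  |x[i+d*tau] - x[nn+d*tau]| / D > A, skipped (and
// counted in n_zero_denom) when D == 0.
// Test 2 (size test):   sqrt(D^2 + extra^2) / sigma > B.
// [[Rcpp::export]]
List fnn_dim(NumericVector x, int d, int tau, double A, double B,
             int theiler, double sigma) {
  const int N = x.size();
  const int M = N - d * tau;
  if (M < 2) stop("series too short for this embedding dimension");

  long long n_used = 0, n1 = 0, n2 = 0, ncomb = 0, nzero = 0;

  for (int i = 0; i < M; ++i) {
    double best = R_PosInf;
    int nn = -1;
    for (int j = 0; j < M; ++j) {
      if (std::abs(i - j) <= theiler) continue;
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        double diff = x[i + k * tau] - x[j + k * tau];
        s += diff * diff;
        if (s >= best) break;  // early abandon (strict < keeps smallest index on ties)
      }
      if (s < best) { best = s; nn = j; }
    }
    if (nn < 0) continue;  // no eligible neighbor (degenerate tiny series)
    n_used += 1;

    double D = std::sqrt(best);
    double extra = std::abs(x[i + d * tau] - x[nn + d * tau]);
    bool t1 = false, t2 = false;
    if (D > 0.0) {
      t1 = (extra / D) > A;
    } else {
      nzero += 1;
    }
    t2 = (std::sqrt(D * D + extra * extra) / sigma) > B;
    if (t1) n1 += 1;
    if (t2) n2 += 1;
    if (t1 || t2) ncomb += 1;
  }

  double denom = (n_used > 0) ? (double)n_used : NA_REAL;
  return List::create(_["fraction_test1"] = n1 / denom,
                      _["fraction_test2"] = n2 / denom,
                      _["fraction_combined"] = ncomb / denom,
                      _["n_pairs"] = (double)n_used,
                      _["n_zero_denom"] = (double)nzero);
}
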