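#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Template-matching counts shared by ApEn, SampEn and expSampEn.
//
// Template starts j = 0..M-1 with M = N - m, so every m-template
// x[j..j+m-1] has an extension point x[j+m].  Matching uses Chebyshev
// distance with "close" meaning <= tol.  Counting conventions:
//
//   cm[q]  = #{ j : max_k |x[j+k] - x[q+k]| <= tol }          (self included)
//   cm1[q] = #{ j counted in cm[q] with |x[j+m] - x[q+m]| <= tol }
//
// expSampEn_q = -log(cm1[q]/cm[q]); both counts include the self-match so
// 1 <= cm1 <= cm and every value is finite and >= 0.  SampEn pair counts
// follow from the symmetry of the match relation (self-matches removed):
// B = (sum cm - M)/2, A = (sum cm1 - M)/2.
//
// Two exact accelerations over the naive O(N^2) scan (results identical):
//   1. duplicate compression - identical (m+1)-tuples are grouped and
//      counted with weights (movement data thresholded to 0/1 and then
//      moving-averaged takes few distinct values, so groups are large);
//   2. box-assisted search - unique tuples are hashed on a grid of cell
//      size tol; a Chebyshev match lies within +/-1 cell per coordinate,
//      so only the 3^m adjacent cells are scanned and every candidate is
//      verified against tol.  Degenerate grids (m > 3, huge cell range)
//      fall back to the all-pairs scan over unique tuples.
// [[Rcpp::export]]
List entropy_engine(NumericVector x, int m, double tol) {
  const int N = x.size();
  const int M = N - m;
  if (M < 2) stop("series too short for template length m");
  if (!(tol > 0)) stop("tolerance must be positive");
  const int W = m + 1;  // tuple width: template + extension point

  // --- group identical (m+1)-tuples -----------------------------------
  std::vector<int> ord(M);
  for (int j = 0; j < M; ++j) ord[j] = j;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    for (int k = 0; k < W; ++k) {
      if (x[a + k] < x[b + k]) return true;
      if (x[a + k] > x[b + k]) return false;
    }
    return false;
  });
  std::vector<int> gid(M);
  std::vector<int> rep;    // representative start index per unique tuple
  std::vector<long long> w;  // group sizes
  for (int i = 0; i < M; ++i) {
    int j = ord[i];
    bool same = false;
    if (i > 0) {
      int p = ord[i - 1];
      same = true;
      for (int k = 0; k < W; ++k) {
        if (x[j + k] != x[p + k]) { same = false; break; }
      }
    }
    if (!same) { rep.push_back(j); w.push_back(0); }
    gid[j] = (int)rep.size() - 1;
    w.back() += 1;
  }
  const int U = (int)rep.size();

  std::vector<long long> cm_u(U, 0), cm1_u(U, 0);

  auto accumulate_pair = [&](int a, int b) {
    // groups a, b (possibly equal) with matching m-templates
    bool ext = std::fabs(x[rep[a] + m] - x[rep[b] + m]) <= tol;
    if (a == b) {
      cm_u[a] += w[a];
      if (ext) cm1_u[a] += w[a];
    } else {
      cm_u[a] += w[b]; cm_u[b] += w[a];
      if (ext) { cm1_u[a] += w[b]; cm1_u[b] += w[a]; }
    }
  };
  auto match_m = [&](int a, int b) {
    for (int k = 0; k < m; ++k) {
      if (std::fabs(x[rep[a] + k] - x[rep[b] + k]) > tol) return false;
    }
    return true;
  };

  // --- grid feasibility ------------------------------------------------
  bool boxed = (m >= 1 && m <= 3);
  long long cmin[3] = {0, 0, 0}, rng[3] = {0, 0, 0};
  std::vector<long long> cell;
  if (boxed) {
    cell.assign((size_t)U * m, 0);
    for (int k = 0; k < m && boxed; ++k) {
      long long lo = 0, hi = 0;
      for (int u = 0; u < U; ++u) {
        long long c = (long long)std::floor(x[rep[u] + k] / tol);
        cell[(size_t)u * m + k] = c;
        if (u == 0) { lo = hi = c; }
        else { if (c < lo) lo = c; if (c > hi) hi = c; }
      }
      cmin[k] = lo; rng[k] = hi - lo + 3;  // room for the +/-1 shells
      if (rng[k] > (1LL << 20)) boxed = false;
    }
  }

  if (!boxed) {
    for (int a = 0; a < U; ++a) {
      accumulate_pair(a, a);
      for (int b = a + 1; b < U; ++b) {
        if (match_m(a, b)) accumulate_pair(a, b);
      }
    }
  } else {
    std::vector<long long> key(U);
    for (int u = 0; u < U; ++u) {
      long long kk = 0;
      for (int k = 0; k < m; ++k) {
        kk = kk * rng[k] + (cell[(size_t)u * m + k] - cmin[k] + 1);
      }
      key[u] = kk;
    }
    std::unordered_map<long long, std::vector<int>> buckets;
    buckets.reserve((size_t)U * 2);
    for (int u = 0; u < U; ++u) buckets[key[u]].push_back(u);

    int ncombo = 1;
    for (int k = 0; k < m; ++k) ncombo *= 3;
    std::vector<long long> offs(ncombo);
    for (int c = 0; c < ncombo; ++c) {
      int cc = c;
      long long off = 0, mult = 1;
      for (int k = m - 1; k >= 0; --k) {
        off += (long long)(cc % 3 - 1) * mult;
        mult *= rng[k];
        cc /= 3;
      }
      offs[c] = off;
    }

    for (int a = 0; a < U; ++a) {
      accumulate_pair(a, a);
      for (int c = 0; c < ncombo; ++c) {
        auto it = buckets.find(key[a] + offs[c]);
        if (it == buckets.end()) continue;
        for (int b : it->second) {
          if (b <= a) continue;  // unordered pairs once; (a,a) handled above
          if (match_m(a, b)) accumulate_pair(a, b);
        }
      }
    }
  }

  // --- expand group counts back to per-point values --------------------
  NumericVector exps(M);
  long long sum_cm = 0, sum_cm1 = 0;
  for (int j = 0; j < M; ++j) {
    int g = gid[j];
    exps[j] = -std::log((double)cm1_u[g] / (double)cm_u[g]);
  }
  for (int u = 0; u < U; ++u) {
    sum_cm += w[u] * cm_u[u];
    sum_cm1 += w[u] * cm1_u[u];
  }
  double B = (double)(sum_cm - M) / 2.0;
  double A = (double)(sum_cm1 - M) / 2.0;

  return List::create(_["exps"] = exps, _["B"] = B, _["A"] = A);
}
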