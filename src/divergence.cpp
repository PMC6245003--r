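#include <Rcpp.h>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Nearest-neighbour log-divergence curve (Rosenstein-style).
//
// For each state i, the Euclidean nearest neighbour j with |i - j| > theiler
// is located; the curve value at lag dt is the mean over pairs of
// log || x[i + dt] - x[j + dt] ||, pairs being dropped once either index
// leaves the series. Distances are floored at 1e-300 before the log so that
// exactly recurrent (periodic) trajectories yield a finite flat curve.
// Ties in the neighbour search resolve to the smallest index, which keeps
// the result deterministic.
// [[Rcpp::export]]
List divergence_curve_cpp(NumericMatrix states, int theiler, int horizon) {
  const int n = states.nrow();
  const int m = states.ncol();
  std::vector<int> nn(n, -1);

  for (int i = 0; i < n; ++i) {
    double best = std::numeric_limits<double>::infinity();
    int best_j = -1;
    for (int j = 0; j < n; ++j) {
      int sep = i - j;
      if (sep < 0) sep = -sep;
      if (sep <= theiler) continue;
      double d2 = 0.0;
      for (int k = 0; k < m; ++k) {
        const double diff = states(i, k) - states(j, k);
        d2 += diff * diff;
        if (d2 >= best) break;
      }
      if (d2 < best) {
        best = d2;
        best_j = j;
      }
    }
    nn[i] = best_j;
  }

  NumericVector curve(horizon + 1);
  IntegerVector counts(horizon + 1);
  for (int dt = 0; dt <= horizon; ++dt) {
    double acc = 0.0;
    int cnt = 0;
    for (int i = 0; i < n; ++i) {
      const int j = nn[i];
      if (j < 0) continue;
      if (i + dt >= n || j + dt >= n) continue;
      double d2 = 0.0;
      for (int k = 0; k < m; ++k) {
        const double diff = states(i + dt, k) - states(j + dt, k);
        d2 += diff * diff;
      }
      double d = std::sqrt(d2);
      if (d < 1e-300) d = 1e-300;
      acc += std::log(d);
      ++cnt;
    }
    curve[dt] = cnt > 0 ? acc / cnt : NA_REAL;
    counts[dt] = cnt;
  }
  return List::create(_["curve"] = curve, _["n_pairs"] = counts);
}
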