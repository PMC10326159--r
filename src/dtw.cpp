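#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Unconstrained DTW dynamic program with Euclidean local cost and steps
// (1,0), (0,1), (1,1). Two-row rolling buffer keeps memory O(m); the cell
// counter is returned so callers can reason about work done, not wall time.
// [[Rcpp::export]]
List dtw_dp(NumericMatrix a, NumericMatrix b) {
  const int n = a.nrow(), m = b.nrow(), d = a.ncol();
  std::vector<double> prev(m), cur(m);
  double ops = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double c = 0.0;
      for (int k = 0; k < d; ++k) {
        const double diff = a(i, k) - b(j, k);
        c += diff * diff;
      }
      c = std::sqrt(c);
      double best;
      if (i == 0 && j == 0) {
        best = 0.0;
      } else if (i == 0) {
        best = cur[j - 1];
      } else if (j == 0) {
        best = prev[0];
      } else {
        best = std::min(prev[j - 1], std::min(prev[j], cur[j - 1]));
      }
      cur[j] = c + best;
      ops += 1.0;
    }
    std::swap(prev, cur);
  }
  return List::create(_["distance"] = prev[m - 1], _["ops"] = ops);
}
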