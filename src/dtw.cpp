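#include <Rcpp.h>
using namespace Rcpp;

// Symmetric DTW with absolute-difference local cost, steps {diag, left, up}.
// Returns alignment cost divided by the number of cells on the optimal path;
// among equal-cost predecessors the one giving the shortest path is kept, so
// the normalization is the minimum path length over minimum-cost paths.
// [[Rcpp::export]]
double dtw_norm_cpp(NumericVector a, NumericVector b) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence in DTW");
  std::vector<double> prev(m), cur(m);
  std::vector<int> lprev(m), lcur(m);

  prev[0] = std::abs(a[0] - b[0]);
  lprev[0] = 1;
  for (int j = 1; j < m; ++j) {
    prev[j] = prev[j - 1] + std::abs(a[0] - b[j]);
    lprev[j] = j + 1;
  }
  for (int i = 1; i < n; ++i) {
    cur[0] = prev[0] + std::abs(a[i] - b[0]);
    lcur[0] = i + 1;
    for (int j = 1; j < m; ++j) {
      const double c = std::abs(a[i] - b[j]);
      double best = prev[j - 1];          // diagonal
      int blen = lprev[j - 1];
      if (prev[j] < best || (prev[j] == best && lprev[j] < blen)) {
        best = prev[j]; blen = lprev[j];  // up
      }
      if (cur[j - 1] < best || (cur[j - 1] == best && lcur[j - 1] < blen)) {
        best = cur[j - 1]; blen = lcur[j - 1];  // left
      }
      cur[j] = best + c;
      lcur[j] = blen + 1;
    }
    std::swap(prev, cur);
    std::swap(lprev, lcur);
  }
  return prev[m - 1] / static_cast<double>(lprev[m - 1]);
}
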