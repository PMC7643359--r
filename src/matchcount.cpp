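#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <vector>

using namespace Rcpp;

// Per-row counts of other rows within Chebyshev distance <= r.
// Rows are sorted by their first coordinate so that only a sliding window
// of candidates has to be inspected; the remaining coordinates are checked
// with early exit. Exact (ties at exactly r count as matches), O(n * w)
// where w is the typical window width.
// [[Rcpp::export]]
IntegerVector cheb_match_counts(NumericMatrix V, double r) {
  const int n = V.nrow(), d = V.ncol();
  if (n == 0) return IntegerVector(0);
  // row-major copy for cache-friendly access
  std::vector<double> X((size_t)n * d);
  for (int j = 0; j < d; ++j)
    for (int i = 0; i < n; ++i)
      X[(size_t)i * d + j] = V(i, j);

  std::vector<int> ord(n);
  std::iota(ord.begin(), ord.end(), 0);
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    return X[(size_t)a * d] < X[(size_t)b * d];
  });

  IntegerVector out(n);
  for (int a = 0; a < n; ++a) {
    const double *xa = &X[(size_t)ord[a] * d];
    for (int b = a + 1; b < n; ++b) {
      const double *xb = &X[(size_t)ord[b] * d];
      if (xb[0] - xa[0] > r) break;
      bool match = true;
      for (int j = 1; j < d; ++j) {
        double diff = xa[j] - xb[j];
        if (diff > r || diff < -r) { match = false; break; }
      }
      if (match) { ++out[ord[a]]; ++out[ord[b]]; }
    }
  }
  return out;
}
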