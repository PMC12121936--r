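#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Centered rolling quantile with truncated edge windows.
// Window at i (0-based) covers [max(0, i - half), min(n - 1, i + half)].
// Quantile follows R's type-7 definition so results match
// stats::quantile(x, prob, type = 7) exactly on every window.
// [[Rcpp::export(name = ".roll_quantile_cpp")]]
NumericVector roll_quantile_cpp(NumericVector x, int half, double prob) {
  const int n = x.size();
  NumericVector out(n);
  std::vector<double> w;  // sorted window contents
  w.reserve(2 * half + 2);

  int lo = 0, hi = -1;  // current window bounds, inclusive
  for (int i = 0; i < n; ++i) {
    int new_lo = std::max(0, i - half);
    int new_hi = std::min(n - 1, i + half);
    while (hi < new_hi) {
      ++hi;
      w.insert(std::upper_bound(w.begin(), w.end(), x[hi]), x[hi]);
    }
    while (lo < new_lo) {
      w.erase(std::lower_bound(w.begin(), w.end(), x[lo]));
      ++lo;
    }
    const int m = static_cast<int>(w.size());
    const double h = (m - 1) * prob;
    const int k = static_cast<int>(std::floor(h));
    double q = w[k];
    if (k + 1 < m) q += (h - k) * (w[k + 1] - w[k]);
    out[i] = q;
  }
  return out;
}
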