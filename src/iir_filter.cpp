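#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Direct-form-II-transposed IIR filter with explicit initial state, the
// building block for zero-phase (forward-backward) filtering with
// steady-state initial conditions. Coefficients must already be normalized
// so a[0] == 1.
// [[Rcpp::export(name = ".iir_filter_cpp")]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a,
                             NumericVector x, NumericVector zi) {
  const int n = x.size();
  const int nf = std::max(a.size(), b.size());
  std::vector<double> bb(nf, 0.0), aa(nf, 0.0), z(nf - 1, 0.0);
  for (int i = 0; i < b.size(); ++i) bb[i] = b[i];
  for (int i = 0; i < a.size(); ++i) aa[i] = a[i];
  for (int i = 0; i < std::min<int>(zi.size(), nf - 1); ++i) z[i] = zi[i];
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = bb[0] * xi + z[0];
    for (int j = 1; j < nf - 1; ++j) {
      z[j - 1] = bb[j] * xi + z[j] - aa[j] * yi;
    }
    z[nf - 2] = bb[nf - 1] * xi - aa[nf - 1] * yi;
    y[i] = yi;
  }
  return y;
}
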