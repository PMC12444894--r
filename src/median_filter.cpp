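#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Centered running median with NA handling: a missing centre sample stays
// missing (blink structure is preserved for the deblink stage); otherwise
// the median is taken over the non-missing values in the window.  Edges use
// shrunken (truncated) windows.
// [[Rcpp::export(rng = false)]]
NumericVector running_median_na(NumericVector x, int window) {
  if (window < 1 || window % 2 == 0)
    stop("window must be a positive odd integer");
  int n = x.size();
  int h = window / 2;
  NumericVector out(n);
  const double *px = REAL(x);
  double *pout = REAL(out);
  std::vector<double> buf(window);
  for (int i = 0; i < n; ++i) {
    if (ISNAN(px[i])) {
      pout[i] = NA_REAL;
      continue;
    }
    int lo = i - h > 0 ? i - h : 0;
    int hi = i + h < n - 1 ? i + h : n - 1;
    int m = 0;
    for (int j = lo; j <= hi; ++j)
      if (!ISNAN(px[j])) buf[m++] = px[j];
    std::nth_element(buf.begin(), buf.begin() + m / 2, buf.begin() + m);
    double med = buf[m / 2];
    if (m % 2 == 0) {
      double lower = *std::max_element(buf.begin(), buf.begin() + m / 2);
      med = (med + lower) / 2.0;
    }
    pout[i] = med;
  }
  return out;
}
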