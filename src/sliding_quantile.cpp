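#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Sliding-window quantile with truncated (not reflected) edge windows.
// Quantile uses linear interpolation between order statistics (the
// default type-7 definition): h = (m - 1) * q over the m in-window
// samples, value = x[floor(h)] + (h - floor(h)) * (x[floor(h)+1] - x[floor(h)]).
// [[Rcpp::export(name = ".sliding_quantile_cpp")]]
NumericVector sliding_quantile_cpp(NumericVector x, int half_window, double q) {
  const int n = x.size();
  if (n < 1) stop("empty input");
  if (half_window < 0) stop("half_window must be >= 0");
  if (q < 0.0 || q > 1.0) stop("quantile must be in [0, 1]");
  NumericVector out(n);
  std::vector<double> buf;
  buf.reserve(2 * half_window + 1);
  for (int t = 0; t < n; ++t) {
    const int lo = std::max(0, t - half_window);
    const int hi = std::min(n - 1, t + half_window);
    const int m = hi - lo + 1;
    buf.assign(x.begin() + lo, x.begin() + hi + 1);
    const double h = (m - 1) * q;
    const int k = (int)std::floor(h);
    std::nth_element(buf.begin(), buf.begin() + k, buf.end());
    const double xk = buf[k];
    double val = xk;
    if (k + 1 <= m - 1 && h > k) {
      const double xk1 = *std::min_element(buf.begin() + k + 1, buf.end());
      val = xk + (h - k) * (xk1 - xk);
    }
    out[t] = val;
  }
  return out;
}
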