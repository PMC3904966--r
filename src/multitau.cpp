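#include <Rcpp.h>
using namespace Rcpp;

// Normalized cross-correlation at one integer lag of two (coarsened)
// traces, with symmetric normalization over the overlap window:
//   g(k) = <a(t) b(t+k)> / (<a(t)> <b(t+k)>) - 1 ,  t = 0..n-k-1.
// Zero-mean windows (empty traces) return 0.
static double xcorr_at(const std::vector<double>& a,
                       const std::vector<double>& b, int k) {
  int n = (int)a.size() - k;
  if (n <= 1) return NA_REAL;
  double sab = 0, sa = 0, sb = 0;
  for (int t = 0; t < n; ++t) {
    sab += a[t] * b[t + k];
    sa += a[t];
    sb += b[t + k];
  }
  double ma = sa / n, mb = sb / n;
  if (ma == 0.0 || mb == 0.0) return 0.0;
  return (sab / n) / (ma * mb) - 1.0;
}

// Multi-tau ladder: level 0 evaluates lags 1..m in raw bins; every further
// level sums adjacent pairs of bins (factor-2 coarsening) and evaluates
// lags m/2+1..m in coarse bins, giving a quasi-logarithmic lag grid.
// [[Rcpp::export(name = ".cpp_multi_tau")]]
List cpp_multi_tau(NumericVector channel_1, NumericVector channel_2,
                   double bin_width, int n_levels, int bins_per_level) {
  std::vector<double> a(channel_1.begin(), channel_1.end());
  std::vector<double> b(channel_2.begin(), channel_2.end());
  std::vector<double> lags, g;
  int m = bins_per_level;
  double dt = bin_width;
  bool truncated = false;

  for (int level = 0; level < n_levels; ++level) {
    int k_lo = (level == 0) ? 1 : m / 2 + 1;
    if ((int)a.size() <= m + 1) { truncated = true; break; }
    for (int k = k_lo; k <= m; ++k) {
      double val = xcorr_at(a, b, k);
      if (!ISNA(val)) {
        lags.push_back(k * dt);
        g.push_back(val);
      }
    }
    if (level + 1 >= n_levels) break;
    // coarsen by 2 (sum of counts); drop a trailing odd bin
    size_t half = a.size() / 2;
    if (half <= (size_t)(m + 1)) { truncated = true; break; }
    for (size_t i = 0; i < half; ++i) {
      a[i] = a[2 * i] + a[2 * i + 1];
      b[i] = b[2 * i] + b[2 * i + 1];
    }
    a.resize(half);
    b.resize(half);
    dt *= 2;
  }
  return List::create(_["lags"] = wrap(lags), _["g"] = wrap(g),
                      _["truncated"] = truncated);
}
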