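#include <Rcpp.h>
using namespace Rcpp;

// Brownian photon-trace simulation: molecules random-walk in a periodic box
// through a 3D-Gaussian detection profile, each carrying a two-state
// bright/dark telegraph process (exact two-state propagator per bin, so the
// state autocorrelation is exactly exp(-(k_dark+k_bright) tau) at bin
// multiples). Photon counts per bin are Poisson; counts are split
// binomially (p = 0.5) between the two detector channels, emulating a
// 50/50 beamsplitter for pseudo-crosscorrelation. Uses R's RNG so set.seed
// gives bit-reproducible traces.
//
// Positions (and the cached detection weight) are advanced every
// pos_update_every bins with a correspondingly scaled diffusion step;
// translational motion is slow on the bin timescale so this is a pure
// speed knob.
// [[Rcpp::export(name = ".cpp_photon_trace")]]
List cpp_photon_trace(int n_bins, double dt, int n_molecules,
                      double w_xy, double w_z,
                      double box_x, double box_y, double box_z,
                      double step_sd, double k_dark, double k_bright,
                      double brightness, double background,
                      int pos_update_every) {
  IntegerVector ch1(n_bins), ch2(n_bins);
  std::vector<double> x(n_molecules), y(n_molecules), z(n_molecules);
  std::vector<double> psf(n_molecules);
  std::vector<int> bright(n_molecules);

  const double k_sum = k_dark + k_bright;
  const double f_dark = k_sum > 0 ? k_dark / k_sum : 0.0;
  const double relax = k_sum > 0 ? 1.0 - std::exp(-k_sum * dt) : 0.0;
  // exact two-state propagator over one bin
  const double p_b2d = f_dark * relax;         // bright -> dark
  const double p_d2b = (1.0 - f_dark) * relax; // dark -> bright
  const double step = step_sd * std::sqrt((double)pos_update_every);

  for (int m = 0; m < n_molecules; ++m) {
    x[m] = R::runif(-box_x / 2, box_x / 2);
    y[m] = R::runif(-box_y / 2, box_y / 2);
    z[m] = R::runif(-box_z / 2, box_z / 2);
    bright[m] = R::unif_rand() < f_dark ? 0 : 1;
    psf[m] = std::exp(-2.0 * (x[m] * x[m] + y[m] * y[m]) / (w_xy * w_xy)
                      - 2.0 * z[m] * z[m] / (w_z * w_z));
  }

  auto wrap = [](double v, double half) {
    while (v > half) v -= 2 * half;
    while (v < -half) v += 2 * half;
    return v;
  };

  for (int t = 0; t < n_bins; ++t) {
    double rate = background;
    bool move = (t % pos_update_every) == 0;
    for (int m = 0; m < n_molecules; ++m) {
      if (move) {
        x[m] = wrap(x[m] + step * R::norm_rand(), box_x / 2);
        y[m] = wrap(y[m] + step * R::norm_rand(), box_y / 2);
        z[m] = wrap(z[m] + step * R::norm_rand(), box_z / 2);
        psf[m] = std::exp(-2.0 * (x[m] * x[m] + y[m] * y[m]) / (w_xy * w_xy)
                          - 2.0 * z[m] * z[m] / (w_z * w_z));
      }
      if (k_sum > 0) {
        double u = R::unif_rand();
        if (bright[m]) {
          if (u < p_b2d) bright[m] = 0;
        } else {
          if (u < p_d2b) bright[m] = 1;
        }
      }
      if (bright[m]) rate += brightness * psf[m];
    }
    int n = (int)R::rpois(rate * dt);
    int n1 = n > 0 ? (int)R::rbinom(n, 0.5) : 0;
    ch1[t] = n1;
    ch2[t] = n - n1;
  }
  return List::create(_["channel_1"] = ch1, _["channel_2"] = ch2);
}
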