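#include <Rcpp.h>
using namespace Rcpp;

// Hot loops of the unisensory likelihood path. Both kernels mirror the
// trapezoidal quadrature of the R implementation; the only numerical
// difference is that Gaussian likelihood terms beyond 9 SDs (relative
// magnitude < 1e-17) are skipped.

static const double INV_SQRT_2PI = 0.3989422804014327;

// Posterior mean E[s | x] on the stimulus grid for each measurement x.
// pw = prior density times trapezoid weights; sig = sigma(s) on the grid.
// Degenerate posteriors (zero mass) are clamped to the signed support edge;
// the caller re-checks and warns.
// [[Rcpp::export]]
NumericVector cpp_post_mean(NumericVector x, NumericVector s_grid,
                            NumericVector sig, NumericVector pw) {
  const int nx = x.size(), ns = s_grid.size();
  NumericVector out(nx);
  const double edge = std::max(std::abs(s_grid[0]), std::abs(s_grid[ns - 1]));
  for (int i = 0; i < nx; ++i) {
    double num = 0.0, den = 0.0;
    const double xi = x[i];
    for (int j = 0; j < ns; ++j) {
      const double z = (xi - s_grid[j]) / sig[j];
      if (z > 9.0 || z < -9.0) continue;
      const double lik = std::exp(-0.5 * z * z) / sig[j] * pw[j];
      den += lik;
      num += lik * s_grid[j];
    }
    out[i] = den > 0.0 ? num / den : (xi >= 0 ? edge : -edge);
  }
  return out;
}

// Response density of unisensory localization trials. For each trial
// (s[i], r[i]): integrate over measurement nodes x = s + u * sig_s, map to
// the internal measurement m = clamp(gain * x), look up the tabulated
// posterior mean by linear interpolation, and accumulate the motor-noise
// Gaussian; the lapse mixture is applied by the caller.
// [[Rcpp::export]]
NumericVector cpp_unisensory_density(NumericVector s, NumericVector r,
                                     NumericVector sig_s, NumericVector u,
                                     NumericVector w, double gain,
                                     double meas_cap, double tab_x0,
                                     double tab_h, NumericVector tab,
                                     double sigma_motor) {
  const int n = s.size(), nu = u.size(), nt = tab.size();
  NumericVector out(n);
  const double inv_sm = 1.0 / sigma_motor;
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    const double si = s[i], ri = r[i], sgi = sig_s[i];
    for (int k = 0; k < nu; ++k) {
      double m = gain * (si + u[k] * sgi);
      if (m > meas_cap) m = meas_cap;
      if (m < -meas_cap) m = -meas_cap;
      double t = (m - tab_x0) / tab_h;
      if (t < 0.0) t = 0.0;
      if (t > nt - 1.000000001) t = nt - 1.000000001;
      const int j = (int)t;
      const double f = t - j;
      const double shat = tab[j] * (1.0 - f) + tab[j + 1] * f;
      const double z = (ri - shat) * inv_sm;
      if (z > 9.0 || z < -9.0) continue;
      acc += w[k] * std::exp(-0.5 * z * z);
    }
    out[i] = acc * INV_SQRT_2PI * inv_sm;
  }
  return out;
}
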