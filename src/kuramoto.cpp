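#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama integration of a mean-field (Kuramoto) phase ensemble with
// per-channel natural frequencies, an optional fixed-adjacency local
// coupling term, and Wiener phase noise.
//
//   dphi_i = [ 2*pi*f_i + g_i * (K/n) * sum_j sin(phi_j - phi_i)
//              + g_i * (K_loc/deg_i) * sum_j A_ij sin(phi_j - phi_i) ] dt
//            + sigma * sqrt(dt) * dW_i
//
// g_i is a per-channel coupling gain (recruitment): channels with g_i < 1
// are only partially entrained by the ensemble.
//
// Uses R's RNG so results are reproducible under set.seed().
// Returned phases are unwrapped; column t holds the state *before* update t,
// so column 1 is phi0 exactly.
// [[Rcpp::export]]
NumericMatrix kuramoto_integrate(int n_channels, int n_samples, double dt,
                                 NumericVector f_channel, double k_global,
                                 NumericMatrix adjacency, double k_local,
                                 double sigma_phi, NumericVector phi0,
                                 NumericVector gain) {
  NumericMatrix phases(n_channels, n_samples);
  std::vector<double> phi(phi0.begin(), phi0.end());
  std::vector<double> dphi(n_channels);
  const double noise_scale = sigma_phi * std::sqrt(dt);
  const bool has_local = (k_local > 0.0) && (adjacency.nrow() == n_channels);

  std::vector<double> deg(n_channels, 1.0);
  if (has_local) {
    for (int i = 0; i < n_channels; ++i) {
      double d = 0.0;
      for (int j = 0; j < n_channels; ++j) d += adjacency(i, j);
      deg[i] = (d > 0.0) ? d : 1.0;
    }
  }

  for (int t = 0; t < n_samples; ++t) {
    for (int i = 0; i < n_channels; ++i) phases(i, t) = phi[i];

    // mean-field resultant: sum_j sin(phi_j - phi_i) = si*cos(phi_i) - sr*sin(phi_i)
    double sr = 0.0, si = 0.0;
    for (int j = 0; j < n_channels; ++j) {
      sr += std::cos(phi[j]);
      si += std::sin(phi[j]);
    }
    for (int i = 0; i < n_channels; ++i) {
      double drive = (k_global / n_channels) *
        (si * std::cos(phi[i]) - sr * std::sin(phi[i]));
      if (has_local) {
        double loc = 0.0;
        for (int j = 0; j < n_channels; ++j) {
          double a = adjacency(i, j);
          if (a > 0.0) loc += a * std::sin(phi[j] - phi[i]);
        }
        drive += (k_local / deg[i]) * loc;
      }
      dphi[i] = 2.0 * M_PI * f_channel[i] + gain[i] * drive;
    }
    for (int i = 0; i < n_channels; ++i) {
      phi[i] += dphi[i] * dt + noise_scale * norm_rand();
    }
  }
  return phases;
}
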