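#include <Rcpp.h>
using namespace Rcpp;

// Accumulate pulse-echo contributions of point scatterers onto one channel's
// fast-time trace. tau: two-way envelope (group) delay per scatterer [s];
// amp: linear amplitude; psi: carrier phase offset so the contribution is
// amp * env(t - tau) * cos(2*pi*f0*(t - tau) + psi).
// env_type: 0 = hann over [-tp/2, tp/2], 1 = gaussian (sigma = tp/4).
// [[Rcpp::export]]
NumericVector rf_deposit(NumericVector tau, NumericVector amp, NumericVector psi,
                         double t0, double dt, int nt, double f0, double tp,
                         int env_type, NumericVector out) {
  if (out.size() != nt) stop("output buffer size mismatch");
  const double half = tp / 2.0;
  const double w0 = 2.0 * M_PI * f0;
  const int n = tau.size();
  for (int s = 0; s < n; ++s) {
    const double tc = tau[s];
    int i0 = (int)std::ceil((tc - half - t0) / dt);
    int i1 = (int)std::floor((tc + half - t0) / dt);
    if (i0 < 0) i0 = 0;
    if (i1 > nt - 1) i1 = nt - 1;
    const double a = amp[s], ph = psi[s];
    for (int i = i0; i <= i1; ++i) {
      const double tr = t0 + i * dt - tc;
      double env;
      if (env_type == 0) {
        env = 0.5 * (1.0 + std::cos(2.0 * M_PI * tr / tp));
      } else {
        const double sg = tp / 4.0;
        env = std::exp(-0.5 * (tr / sg) * (tr / sg));
      }
      out[i] += a * env * std::cos(w0 * tr + ph);
    }
  }
  return out;
}
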