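// Single-site Gibbs sampler for a mixed graphical model given its nodewise
// linear conditionals. State is kept on the standardized scale; ordinal
// nodes are clipped to their code range and rounded at each update, and the
// discretized value re-enters the conditionals of the other nodes.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix gibbs_mgm_cpp(const NumericMatrix& B,          // row i: coefs of node i on others (std scale)
                            const NumericVector& intercept,  // std-scale intercepts
                            const NumericVector& sigma,      // residual sd, std scale
                            const NumericVector& center,     // training means (raw scale)
                            const NumericVector& scale,      // training sds (raw scale)
                            const LogicalVector& ordinal,
                            const NumericVector& code_min,
                            const NumericVector& code_max,
                            const LogicalVector& clamped,
                            const NumericVector& clamp_raw,
                            const NumericVector& init_raw,
                            int n_samples, int burn_in, int thin) {
  const int p = B.nrow();
  std::vector<double> x(p);        // standardized state
  std::vector<double> raw(p);      // raw-scale state
  for (int i = 0; i < p; ++i) {
    raw[i] = clamped[i] ? clamp_raw[i] : init_raw[i];
    x[i] = (raw[i] - center[i]) / scale[i];
  }

  int n_keep = n_samples / thin;
  NumericMatrix out(n_keep, p);
  int kept = 0;

  int total = burn_in + n_samples;
  for (int s = 0; s < total; ++s) {
    for (int i = 0; i < p; ++i) {
      if (clamped[i]) continue;
      double mu = intercept[i];
      for (int j = 0; j < p; ++j) mu += B(i, j) * x[j];
      double draw = (sigma[i] > 0.0) ? R::rnorm(mu, sigma[i]) : mu;
      double r = center[i] + scale[i] * draw;
      if (ordinal[i]) {
        if (r < code_min[i]) r = code_min[i];
        if (r > code_max[i]) r = code_max[i];
        r = std::floor(r + 0.5);
      }
      raw[i] = r;
      x[i] = (r - center[i]) / scale[i];
    }
    if (s >= burn_in && ((s - burn_in) % thin == 0) && kept < n_keep) {
      for (int i = 0; i < p; ++i) out(kept, i) = raw[i];
      ++kept;
    }
  }
  return out;
}
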