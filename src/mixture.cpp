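#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Log-likelihood of amplitudes under a finite Gaussian mixture with common
// sigma: sum_j w_j * Normal(mu_j, sigma). Hot loop of quantal model
// selection (thousands of trials x N+1 components x many optimizer steps).
// [[Rcpp::export(name = ".mixtureLogLik")]]
double mixtureLogLik(NumericVector x, NumericVector mu, NumericVector w,
                     double sigma) {
  const int n = x.size(), m = mu.size();
  if (sigma <= 0.0) return R_NegInf;
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const double lognorm = -std::log(sigma) - 0.5 * std::log(2.0 * M_PI);
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    const double xi = x[i];
    for (int j = 0; j < m; ++j) {
      const double d = xi - mu[j];
      s += w[j] * std::exp(-d * d * inv2s2);
    }
    ll += std::log(s > 1e-300 ? s : 1e-300);
  }
  return ll + n * lognorm;
}
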