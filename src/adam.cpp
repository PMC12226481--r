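// In-place Adam update; param, m and v are owned exclusively by the layer
// environments, so in-place mutation is safe and avoids per-step
// allocations over every parameter tensor.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
void adam_update(NumericVector param, const NumericVector& grad,
                 NumericVector m, NumericVector v, const double lr,
                 const double beta1, const double beta2, const double eps,
                 const double bc1, const double bc2) {
  const R_xlen_t n = param.size();
  double *pp = param.begin(), *pm = m.begin(), *pv = v.begin();
  const double* pg = grad.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    pm[i] = beta1 * pm[i] + (1.0 - beta1) * pg[i];
    pv[i] = beta2 * pv[i] + (1.0 - beta2) * pg[i] * pg[i];
    pp[i] -= lr * (pm[i] / bc1) / (std::sqrt(pv[i] / bc2) + eps);
  }
}
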