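// Fused elementwise kernels for batch normalisation and ReLU. The R-level
// implementations of these are allocation-bound on the large unit-1 feature
// maps; each function here is a single pass over memory. Layout for BN:
// x viewed as [n, C, B] (channel block c of trial b contiguous at offset
// (b*C + c) * n).

#include <Rcpp.h>
using namespace Rcpp;

// per-channel sums and sums of squares
// [[Rcpp::export]]
List bn_stats(const NumericVector& x, const int n, const int C, const int B) {
  NumericVector s(C), ss(C);
  const double* px = x.begin();
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const double* p = px + ((size_t)b * C + c) * n;
      double a = 0, a2 = 0;
      for (int i = 0; i < n; ++i) {
        a += p[i];
        a2 += p[i] * p[i];
      }
      s[c] += a;
      ss[c] += a2;
    }
  return List::create(_["sum"] = s, _["sumsq"] = ss);
}

// y = gamma * (x - mu) * istd + beta; also returns xhat for the backward
// [[Rcpp::export]]
List bn_apply(const NumericVector& x, const NumericVector& mu,
              const NumericVector& istd, const NumericVector& gamma,
              const NumericVector& beta, const int n, const int C,
              const int B) {
  NumericVector y(x.size()), xhat(x.size());
  const double* px = x.begin();
  double *py = y.begin(), *ph = xhat.begin();
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const size_t o = ((size_t)b * C + c) * n;
      const double m = mu[c], is = istd[c], g = gamma[c], bt = beta[c];
      for (int i = 0; i < n; ++i) {
        const double h = (px[o + i] - m) * is;
        ph[o + i] = h;
        py[o + i] = g * h + bt;
      }
    }
  return List::create(_["y"] = y, _["xhat"] = xhat);
}

// per-channel sums of dout and dout * xhat (dgamma/dbeta and the centring
// terms of the batch-statistics backward)
// [[Rcpp::export]]
List bn_bwd_sums(const NumericVector& dout, const NumericVector& xhat,
                 const int n, const int C, const int B) {
  NumericVector s(C), sh(C);
  const double *pd = dout.begin(), *ph = xhat.begin();
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const size_t o = ((size_t)b * C + c) * n;
      double a = 0, a2 = 0;
      for (int i = 0; i < n; ++i) {
        a += pd[o + i];
        a2 += pd[o + i] * ph[o + i];
      }
      s[c] += a;
      sh[c] += a2;
    }
  return List::create(_["sum"] = s, _["sum_xhat"] = sh);
}

// dx = istd * gamma * (dout - s1 - xhat * s2); with s1 = s2 = 0 this is the
// inference-mode (running statistics) backward
// [[Rcpp::export]]
NumericVector bn_bwd_apply(const NumericVector& dout,
                           const NumericVector& xhat,
                           const NumericVector& gamma,
                           const NumericVector& istd,
                           const NumericVector& s1, const NumericVector& s2,
                           const int n, const int C, const int B) {
  NumericVector dx(dout.size());
  const double *pd = dout.begin(), *ph = xhat.begin();
  double* px = dx.begin();
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const size_t o = ((size_t)b * C + c) * n;
      const double gi = gamma[c] * istd[c], a = s1[c], bb = s2[c];
      for (int i = 0; i < n; ++i)
        px[o + i] = gi * (pd[o + i] - a - ph[o + i] * bb);
    }
  return dx;
}

// [[Rcpp::export]]
NumericVector relu_fwd(const NumericVector& x) {
  NumericVector y(x.size());
  const double* px = x.begin();
  double* py = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) py[i] = px[i] > 0 ? px[i] : 0.0;
  return y;
}

// mask taken from the forward output (y > 0 <=> x > 0 up to exact zeros,
// where the subgradient 0 is used either way)
// [[Rcpp::export]]
NumericVector relu_bwd(const NumericVector& dout, const NumericVector& y) {
  NumericVector dx(dout.size());
  const double *pd = dout.begin(), *py = y.begin();
  double* px = dx.begin();
  for (R_xlen_t i = 0; i < dout.size(); ++i)
    px[i] = py[i] > 0 ? pd[i] : 0.0;
  return dx;
}

// fused batchnorm + ReLU forward: y = max(gamma * xhat + beta, 0)
// [[Rcpp::export]]
List bn_relu_apply(const NumericVector& x, const NumericVector& mu,
                   const NumericVector& istd, const NumericVector& gamma,
                   const NumericVector& beta, const int n, const int C,
                   const int B) {
  NumericVector y(x.size()), xhat(x.size());
  const double* px = x.begin();
  double *py = y.begin(), *ph = xhat.begin();
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const size_t o = ((size_t)b * C + c) * n;
      const double m = mu[c], is = istd[c], g = gamma[c], bt = beta[c];
      for (int i = 0; i < n; ++i) {
        const double h = (px[o + i] - m) * is;
        ph[o + i] = h;
        const double v = g * h + bt;
        py[o + i] = v > 0 ? v : 0.0;
      }
    }
  return List::create(_["y"] = y, _["xhat"] = xhat);
}

// per-channel sums of the ReLU-masked dout and dout * xhat
// [[Rcpp::export]]
List bn_relu_bwd_sums(const NumericVector& dout, const NumericVector& xhat,
                      const NumericVector& y, const int n, const int C,
                      const int B) {
  NumericVector s(C), sh(C);
  const double *pd = dout.begin(), *ph = xhat.begin(), *py = y.begin();
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const size_t o = ((size_t)b * C + c) * n;
      double a = 0, a2 = 0;
      for (int i = 0; i < n; ++i) {
        if (py[o + i] > 0) {
          a += pd[o + i];
          a2 += pd[o + i] * ph[o + i];
        }
      }
      s[c] += a;
      sh[c] += a2;
    }
  return List::create(_["sum"] = s, _["sum_xhat"] = sh);
}

// dx = istd * gamma * (mask * dout - s1 - xhat * s2)
// [[Rcpp::export]]
NumericVector bn_relu_bwd_apply(const NumericVector& dout,
                                const NumericVector& xhat,
                                const NumericVector& y,
                                const NumericVector& gamma,
                                const NumericVector& istd,
                                const NumericVector& s1,
                                const NumericVector& s2, const int n,
                                const int C, const int B) {
  NumericVector dx(dout.size());
  const double *pd = dout.begin(), *ph = xhat.begin(), *py = y.begin();
  double* px = dx.begin();
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const size_t o = ((size_t)b * C + c) * n;
      const double gi = gamma[c] * istd[c], a = s1[c], bb = s2[c];
      for (int i = 0; i < n; ++i) {
        const double dm = py[o + i] > 0 ? pd[o + i] : 0.0;
        px[o + i] = gi * (dm - a - ph[o + i] * bb);
      }
    }
  return dx;
}
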