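// 1D (over time) convolution primitives for the auto-encoder branch.
// Layout: x = [L, C, R] column-major (time fastest), weights [K, Cin, F].

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector conv1d_fwd(const NumericVector& x, const NumericVector& w,
                         const NumericVector& bias, const IntegerVector& xd,
                         const IntegerVector& wd, const int stride,
                         const int pad) {
  const int L = xd[0], C = xd[1], R = xd[2];
  const int K = wd[0], CI = wd[1], F = wd[2];
  if (CI != C) stop("conv1d_fwd: channel mismatch");
  const int Lout = (L + 2 * pad - K) / stride + 1;
  NumericVector out((size_t)Lout * F * R);
  double* po = out.begin();
  const double *px = x.begin(), *pw = w.begin(), *pb = bias.begin();
  for (int r = 0; r < R; ++r)
    for (int f = 0; f < F; ++f) {
      double* o = po + ((size_t)r * F + f) * Lout;
      for (int l = 0; l < Lout; ++l) o[l] = pb[f];
      for (int c = 0; c < C; ++c) {
        const double* xc = px + ((size_t)r * C + c) * L;
        for (int j = 0; j < K; ++j) {
          const double wv = pw[j + K * (c + CI * f)];
          // input index i = l*stride + j - pad in [0, L)
          int l0 = 0;
          while (l0 < Lout && l0 * stride + j - pad < 0) ++l0;
          int l1 = Lout;
          while (l1 > l0 && (l1 - 1) * stride + j - pad >= L) --l1;
          for (int l = l0; l < l1; ++l) o[l] += wv * xc[l * stride + j - pad];
        }
      }
    }
  return out;
}

// [[Rcpp::export]]
List conv1d_bwd(const NumericVector& x, const NumericVector& w,
                const NumericVector& dout, const IntegerVector& xd,
                const IntegerVector& wd, const int stride, const int pad) {
  const int L = xd[0], C = xd[1], R = xd[2];
  const int K = wd[0], CI = wd[1], F = wd[2];
  const int Lout = (L + 2 * pad - K) / stride + 1;
  NumericVector dx((size_t)L * C * R), dw((size_t)K * CI * F), db(F);
  double *pdx = dx.begin(), *pdw = dw.begin(), *pdb = db.begin();
  const double *px = x.begin(), *pw = w.begin(), *pdo = dout.begin();
  for (int r = 0; r < R; ++r)
    for (int f = 0; f < F; ++f) {
      const double* o = pdo + ((size_t)r * F + f) * Lout;
      double acc = 0.0;
      for (int l = 0; l < Lout; ++l) acc += o[l];
      pdb[f] += acc;
      for (int c = 0; c < C; ++c) {
        const double* xc = px + ((size_t)r * C + c) * L;
        double* dxc = pdx + ((size_t)r * C + c) * L;
        for (int j = 0; j < K; ++j) {
          const double wv = pw[j + K * (c + CI * f)];
          int l0 = 0;
          while (l0 < Lout && l0 * stride + j - pad < 0) ++l0;
          int l1 = Lout;
          while (l1 > l0 && (l1 - 1) * stride + j - pad >= L) --l1;
          double wacc = 0.0;
          for (int l = l0; l < l1; ++l) {
            const int i = l * stride + j - pad;
            wacc += o[l] * xc[i];
            dxc[i] += wv * o[l];
          }
          pdw[j + K * (c + CI * f)] += wacc;
        }
      }
    }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// transposed convolution: out[l] += w[j] * x[i] where l = i*stride + j - pad
// [[Rcpp::export]]
NumericVector convt1d_fwd(const NumericVector& x, const NumericVector& w,
                          const NumericVector& bias, const IntegerVector& xd,
                          const IntegerVector& wd, const int stride,
                          const int pad) {
  const int L = xd[0], C = xd[1], R = xd[2];
  const int K = wd[0], CI = wd[1], F = wd[2];
  if (CI != C) stop("convt1d_fwd: channel mismatch");
  const int Lout = (L - 1) * stride - 2 * pad + K;
  NumericVector out((size_t)Lout * F * R);
  double* po = out.begin();
  const double *px = x.begin(), *pw = w.begin(), *pb = bias.begin();
  for (int r = 0; r < R; ++r)
    for (int f = 0; f < F; ++f) {
      double* o = po + ((size_t)r * F + f) * Lout;
      for (int l = 0; l < Lout; ++l) o[l] = pb[f];
      for (int c = 0; c < C; ++c) {
        const double* xc = px + ((size_t)r * C + c) * L;
        for (int j = 0; j < K; ++j) {
          const double wv = pw[j + K * (c + CI * f)];
          for (int i = 0; i < L; ++i) {
            const int l = i * stride + j - pad;
            if (l >= 0 && l < Lout) o[l] += wv * xc[i];
          }
        }
      }
    }
  return out;
}

// [[Rcpp::export]]
List convt1d_bwd(const NumericVector& x, const NumericVector& w,
                 const NumericVector& dout, const IntegerVector& xd,
                 const IntegerVector& wd, const int stride, const int pad) {
  const int L = xd[0], C = xd[1], R = xd[2];
  const int K = wd[0], CI = wd[1], F = wd[2];
  const int Lout = (L - 1) * stride - 2 * pad + K;
  NumericVector dx((size_t)L * C * R), dw((size_t)K * CI * F), db(F);
  double *pdx = dx.begin(), *pdw = dw.begin(), *pdb = db.begin();
  const double *px = x.begin(), *pw = w.begin(), *pdo = dout.begin();
  for (int r = 0; r < R; ++r)
    for (int f = 0; f < F; ++f) {
      const double* o = pdo + ((size_t)r * F + f) * Lout;
      double acc = 0.0;
      for (int l = 0; l < Lout; ++l) acc += o[l];
      pdb[f] += acc;
      for (int c = 0; c < C; ++c) {
        const double* xc = px + ((size_t)r * C + c) * L;
        double* dxc = pdx + ((size_t)r * C + c) * L;
        for (int j = 0; j < K; ++j) {
          const double wv = pw[j + K * (c + CI * f)];
          double wacc = 0.0;
          for (int i = 0; i < L; ++i) {
            const int l = i * stride + j - pad;
            if (l >= 0 && l < Lout) {
              wacc += o[l] * xc[i];
              dxc[i] += wv * o[l];
            }
          }
          pdw[j + K * (c + CI * f)] += wacc;
        }
      }
    }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
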