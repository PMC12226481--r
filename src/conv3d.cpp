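// 3D convolution primitives for the spatial-temporal branch.
//
// Tensor layout (column-major, first index fastest): x = [T, H, W, C, B]
// with the time axis innermost so the hot loops run over contiguous memory.
// Weights: [KT, KH, KW, Cin, F]. All convolutions are stride-1 with "same"
// zero padding and odd kernel extents.
//
// Each kernel exists in double and in float32 (inputs are converted on
// entry); single precision roughly doubles SIMD throughput and is the
// training default for the scaled-down benchmark, while the double path is
// the reference used by gradient checks.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static inline int imax(int a, int b) { return a > b ? a : b; }
static inline int imin(int a, int b) { return a < b ? a : b; }

// runtime-dispatched SIMD clones where supported (x86-64 gcc); plain
// scalar build elsewhere
#if defined(__GNUC__) && defined(__x86_64__) && !defined(__clang__)
#define FNSSIR_CLONES \
  __attribute__((target_clones("default", "arch=x86-64-v3", "arch=x86-64-v4")))
#else
#define FNSSIR_CLONES
#endif

template <typename T>
FNSSIR_CLONES static void axpy_run(T* __restrict o, const T* __restrict x,
                                   const T wv, const int t0, const int t1) {
  for (int t = t0; t < t1; ++t) o[t] += wv * x[t];
}

template <typename T>
FNSSIR_CLONES static T dot_run(const T* __restrict a, const T* __restrict b,
                               const int t0, const int t1) {
  T acc = T(0);
  for (int t = t0; t < t1; ++t) acc += a[t] * b[t];
  return acc;
}

template <typename T>
static std::vector<T> to_vec(const NumericVector& v) {
  std::vector<T> out(v.size());
  const double* p = v.begin();
  for (R_xlen_t i = 0; i < v.size(); ++i) out[i] = (T)p[i];
  return out;
}

template <typename T>
static void conv3d_fwd_t(const T* px, const T* pwt, const T* pb, double* po,
                         const IntegerVector& xd, const IntegerVector& wd,
                         const int Ftot, const int coff) {
  const int Tn = xd[0], H = xd[1], W = xd[2], C = xd[3], B = xd[4];
  const int KT = wd[0], KH = wd[1], KW = wd[2], CI = wd[3], F = wd[4];
  const int pt = (KT - 1) / 2, ph = (KH - 1) / 2, pw = (KW - 1) / 2;
  const size_t xs_h = Tn, xs_w = (size_t)Tn * H, xs_c = (size_t)Tn * H * W,
               xs_b = xs_c * C;
  const size_t os_h = Tn, os_w = (size_t)Tn * H, os_f = (size_t)Tn * H * W;
  const size_t os_b = os_f * Ftot;              // stride between trials
  std::vector<T> obuf(os_f * F);
  for (int b = 0; b < B; ++b) {
    for (int f = 0; f < F; ++f) {
      T* o0 = obuf.data() + f * os_f;
      for (size_t i = 0; i < os_f; ++i) o0[i] = pb[f];
    }
    for (int f = 0; f < F; ++f)
      for (int c = 0; c < C; ++c)
        for (int kw = 0; kw < KW; ++kw) {
          const int w0 = imax(0, pw - kw), w1 = imin(W, W + pw - kw);
          for (int kh = 0; kh < KH; ++kh) {
            const int h0 = imax(0, ph - kh), h1 = imin(H, H + ph - kh);
            for (int kt = 0; kt < KT; ++kt) {
              const T wv =
                  pwt[kt + (size_t)KT * (kh + (size_t)KH * (kw + (size_t)KW * (c + (size_t)CI * f)))];
              if (wv == T(0)) continue;
              const int t0 = imax(0, pt - kt), t1 = imin(Tn, Tn + pt - kt);
              const int d = kt - pt;
              for (int wi = w0; wi < w1; ++wi) {
                const int wx = wi + kw - pw;
                for (int hi = h0; hi < h1; ++hi) {
                  const int hx = hi + kh - ph;
                  const T* xr =
                      px + b * xs_b + c * xs_c + wx * xs_w + hx * xs_h + d;
                  T* orow = obuf.data() + f * os_f + wi * os_w + hi * os_h;
                  axpy_run(orow, xr, wv, t0, t1);
                }
              }
            }
          }
        }
    double* od = po + b * os_b + coff * os_f;
    for (size_t i = 0; i < os_f * F; ++i) od[i] = (double)obuf[i];
  }
}

template <typename T>
static void conv3d_wgrad_t(const T* px, const T* pdo, double* pdw,
                           double* pdb, const IntegerVector& xd,
                           const IntegerVector& wd, const int Ftot,
                           const int coff) {
  const int Tn = xd[0], H = xd[1], W = xd[2], C = xd[3], B = xd[4];
  const int KT = wd[0], KH = wd[1], KW = wd[2], CI = wd[3], F = wd[4];
  const int pt = (KT - 1) / 2, ph = (KH - 1) / 2, pw = (KW - 1) / 2;
  const size_t xs_h = Tn, xs_w = (size_t)Tn * H, xs_c = (size_t)Tn * H * W,
               xs_b = xs_c * C;
  const size_t os_h = Tn, os_w = (size_t)Tn * H, os_f = (size_t)Tn * H * W;
  const size_t os_b = os_f * Ftot;
  for (int b = 0; b < B; ++b)
    for (int f = 0; f < F; ++f) {
      const T* o0 = pdo + b * os_b + (coff + f) * os_f;
      T acc = T(0);
      for (size_t i = 0; i < os_f; ++i) acc += o0[i];
      pdb[f] += (double)acc;
    }
  for (int b = 0; b < B; ++b)
    for (int f = 0; f < F; ++f)
      for (int c = 0; c < C; ++c)
        for (int kw = 0; kw < KW; ++kw) {
          const int w0 = imax(0, pw - kw), w1 = imin(W, W + pw - kw);
          for (int kh = 0; kh < KH; ++kh) {
            const int h0 = imax(0, ph - kh), h1 = imin(H, H + ph - kh);
            for (int kt = 0; kt < KT; ++kt) {
              const int t0 = imax(0, pt - kt), t1 = imin(Tn, Tn + pt - kt);
              const int d = kt - pt;
              T acc = T(0);
              for (int wi = w0; wi < w1; ++wi) {
                const int wx = wi + kw - pw;
                for (int hi = h0; hi < h1; ++hi) {
                  const T* xr =
                      px + b * xs_b + c * xs_c + wx * xs_w + (hi + kh - ph) * xs_h + d;
                  const T* orow =
                      pdo + b * os_b + (coff + f) * os_f + wi * os_w + hi * os_h;
                  acc += dot_run(orow, xr, t0, t1);
                }
              }
              pdw[kt + (size_t)KT * (kh + (size_t)KH * (kw + (size_t)KW * (c + (size_t)CI * f)))] += (double)acc;
            }
          }
        }
}

template <typename T>
static void conv3d_igrad_t(const T* pdo, const T* pwt, double* pdx,
                           const IntegerVector& xd, const IntegerVector& wd,
                           const int Ftot, const int coff) {
  const int Tn = xd[0], H = xd[1], W = xd[2], C = xd[3], B = xd[4];
  const int KT = wd[0], KH = wd[1], KW = wd[2], CI = wd[3], F = wd[4];
  const int pt = (KT - 1) / 2, ph = (KH - 1) / 2, pw = (KW - 1) / 2;
  const size_t xs_h = Tn, xs_w = (size_t)Tn * H, xs_c = (size_t)Tn * H * W,
               xs_b = xs_c * C;
  const size_t os_h = Tn, os_w = (size_t)Tn * H, os_f = (size_t)Tn * H * W;
  const size_t os_b = os_f * Ftot;
  std::vector<T> xbuf(xs_b);
  for (int b = 0; b < B; ++b) {
    std::fill(xbuf.begin(), xbuf.end(), T(0));
    for (int f = 0; f < F; ++f)
      for (int c = 0; c < C; ++c)
        for (int kw = 0; kw < KW; ++kw) {
          const int w0 = imax(0, pw - kw), w1 = imin(W, W + pw - kw);
          for (int kh = 0; kh < KH; ++kh) {
            const int h0 = imax(0, ph - kh), h1 = imin(H, H + ph - kh);
            for (int kt = 0; kt < KT; ++kt) {
              const T wv =
                  pwt[kt + (size_t)KT * (kh + (size_t)KH * (kw + (size_t)KW * (c + (size_t)CI * f)))];
              if (wv == T(0)) continue;
              const int t0 = imax(0, pt - kt), t1 = imin(Tn, Tn + pt - kt);
              const int d = kt - pt;
              for (int wi = w0; wi < w1; ++wi) {
                const int wx = wi + kw - pw;
                for (int hi = h0; hi < h1; ++hi) {
                  T* xr = xbuf.data() + c * xs_c + wx * xs_w +
                          (hi + kh - ph) * xs_h + d;
                  const T* orow =
                      pdo + b * os_b + (coff + f) * os_f + wi * os_w + hi * os_h;
                  axpy_run(xr, orow, wv, t0, t1);
                }
              }
            }
          }
        }
    double* xd_ = pdx + b * xs_b;
    for (size_t i = 0; i < xs_b; ++i) xd_[i] += (double)xbuf[i];
  }
}

// [[Rcpp::export]]
NumericVector conv3d_fwd(const NumericVector& x, const NumericVector& w,
                         const NumericVector& bias, const IntegerVector& xd,
                         const IntegerVector& wd, const bool single = false) {
  NumericVector out((size_t)xd[0] * xd[1] * xd[2] * wd[4] * xd[4]);
  if (single) {
    auto xf = to_vec<float>(x);
    auto wf = to_vec<float>(w);
    auto bf = to_vec<float>(bias);
    conv3d_fwd_t<float>(xf.data(), wf.data(), bf.data(), out.begin(), xd, wd,
                        wd[4], 0);
  } else {
    conv3d_fwd_t<double>(x.begin(), w.begin(), bias.begin(), out.begin(),
                         xd, wd, wd[4], 0);
  }
  return out;
}

// forward writing into channel slice [coff, coff + F) of a pre-allocated
// concat buffer `out` with Ftot output channels (mutated in place)
// [[Rcpp::export]]
void conv3d_fwd_into(NumericVector out, const NumericVector& x,
                     const NumericVector& w, const NumericVector& bias,
                     const IntegerVector& xd, const IntegerVector& wd,
                     const int Ftot, const int coff,
                     const bool single = false) {
  if (single) {
    auto xf = to_vec<float>(x);
    auto wf = to_vec<float>(w);
    auto bf = to_vec<float>(bias);
    conv3d_fwd_t<float>(xf.data(), wf.data(), bf.data(), out.begin(), xd, wd,
                        Ftot, coff);
  } else {
    conv3d_fwd_t<double>(x.begin(), w.begin(), bias.begin(), out.begin(),
                         xd, wd, Ftot, coff);
  }
}

// gradient wrt weights and bias; returns list(dw, db); dout may be a concat
// buffer with Ftot channels, of which [coff, coff + F) belong to this branch
// [[Rcpp::export]]
List conv3d_wgrad(const NumericVector& x, const NumericVector& dout,
                  const IntegerVector& xd, const IntegerVector& wd,
                  const bool single = false, const int Ftot = -1,
                  const int coff = 0) {
  NumericVector dw((size_t)wd[0] * wd[1] * wd[2] * wd[3] * wd[4]);
  NumericVector db(wd[4]);
  const int ft = Ftot < 0 ? wd[4] : Ftot;
  if (single) {
    auto xf = to_vec<float>(x);
    auto df = to_vec<float>(dout);
    conv3d_wgrad_t<float>(xf.data(), df.data(), dw.begin(), db.begin(), xd,
                          wd, ft, coff);
  } else {
    conv3d_wgrad_t<double>(x.begin(), dout.begin(), dw.begin(), db.begin(),
                           xd, wd, ft, coff);
  }
  return List::create(_["dw"] = dw, _["db"] = db);
}

// gradient wrt the input
// [[Rcpp::export]]
NumericVector conv3d_igrad(const NumericVector& dout, const NumericVector& w,
                           const IntegerVector& xd, const IntegerVector& wd,
                           const bool single = false) {
  NumericVector dx((size_t)xd[0] * xd[1] * xd[2] * xd[3] * xd[4]);
  if (single) {
    auto df = to_vec<float>(dout);
    auto wf = to_vec<float>(w);
    conv3d_igrad_t<float>(df.data(), wf.data(), dx.begin(), xd, wd, wd[4], 0);
  } else {
    conv3d_igrad_t<double>(dout.begin(), w.begin(), dx.begin(), xd, wd,
                           wd[4], 0);
  }
  return dx;
}

// input gradient accumulated into a pre-allocated dx buffer (in place);
// dout is a concat buffer with Ftot channels
// [[Rcpp::export]]
void conv3d_igrad_into(NumericVector dx, const NumericVector& dout,
                       const NumericVector& w, const IntegerVector& xd,
                       const IntegerVector& wd, const int Ftot,
                       const int coff, const bool single = false) {
  if (single) {
    auto df = to_vec<float>(dout);
    auto wf = to_vec<float>(w);
    conv3d_igrad_t<float>(df.data(), wf.data(), dx.begin(), xd, wd, Ftot,
                          coff);
  } else {
    conv3d_igrad_t<double>(dout.begin(), w.begin(), dx.begin(), xd, wd,
                           Ftot, coff);
  }
}

// non-overlapping average pooling on [T, H, W, C, B]; pd = (pt, ph, pw)
// [[Rcpp::export]]
NumericVector avgpool3d_fwd(const NumericVector& x, const IntegerVector& xd,
                            const IntegerVector& pd) {
  const int T = xd[0], H = xd[1], W = xd[2], C = xd[3], B = xd[4];
  const int qt = pd[0], qh = pd[1], qw = pd[2];
  if (T % qt || H % qh || W % qw)
    stop("avgpool3d: pool (%d,%d,%d) does not divide extents (%d,%d,%d)",
         qh, qw, qt, H, W, T);
  const int T2 = T / qt, H2 = H / qh, W2 = W / qw;
  const double inv = 1.0 / (qt * qh * qw);
  NumericVector out((size_t)T2 * H2 * W2 * C * B);
  double* po = out.begin();
  const double* px = x.begin();
  const size_t xs_h = T, xs_w = (size_t)T * H, xs_cb = (size_t)T * H * W;
  const size_t os_h = T2, os_w = (size_t)T2 * H2, os_cb = (size_t)T2 * H2 * W2;
  const int CB = C * B;
  for (int cb = 0; cb < CB; ++cb)
    for (int wo = 0; wo < W2; ++wo)
      for (int ho = 0; ho < H2; ++ho) {
        double* orow = po + cb * os_cb + wo * os_w + ho * os_h;
        for (int dw = 0; dw < qw; ++dw)
          for (int dh = 0; dh < qh; ++dh) {
            const double* xr = px + cb * xs_cb + (wo * qw + dw) * xs_w +
                               (ho * qh + dh) * xs_h;
            for (int to = 0; to < T2; ++to) {
              double acc = 0.0;
              const double* xt = xr + to * qt;
              for (int dt = 0; dt < qt; ++dt) acc += xt[dt];
              orow[to] += acc;
            }
          }
        for (int to = 0; to < T2; ++to) orow[to] *= inv;
      }
  return out;
}

// [[Rcpp::export]]
NumericVector avgpool3d_bwd(const NumericVector& dout, const IntegerVector& xd,
                            const IntegerVector& pd) {
  const int T = xd[0], H = xd[1], W = xd[2], C = xd[3], B = xd[4];
  const int qt = pd[0], qh = pd[1], qw = pd[2];
  const int T2 = T / qt, H2 = H / qh, W2 = W / qw;
  const double inv = 1.0 / (qt * qh * qw);
  NumericVector dx((size_t)T * H * W * C * B);
  double* pdx = dx.begin();
  const double* pdo = dout.begin();
  const size_t xs_h = T, xs_w = (size_t)T * H, xs_cb = (size_t)T * H * W;
  const size_t os_h = T2, os_w = (size_t)T2 * H2, os_cb = (size_t)T2 * H2 * W2;
  const int CB = C * B;
  for (int cb = 0; cb < CB; ++cb)
    for (int wo = 0; wo < W2; ++wo)
      for (int ho = 0; ho < H2; ++ho) {
        const double* orow = pdo + cb * os_cb + wo * os_w + ho * os_h;
        for (int dw = 0; dw < qw; ++dw)
          for (int dh = 0; dh < qh; ++dh) {
            double* xr = pdx + cb * xs_cb + (wo * qw + dw) * xs_w +
                         (ho * qh + dh) * xs_h;
            for (int to = 0; to < T2; ++to) {
              const double g = orow[to] * inv;
              double* xt = xr + to * qt;
              for (int dt = 0; dt < qt; ++dt) xt[dt] += g;
            }
          }
      }
  return dx;
}
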