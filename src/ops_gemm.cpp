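// GEMM-based convolution kernels.
//
// Each batch item is lowered to a patch matrix M_b (Ho*Wo x C*k*k); the
// channel mixing is one BLAS gemm per item. Fills, gathers and scatters
// process all batch items per cache line (the batch is the fastest-moving
// array dimension), so memory traffic is streamed. A single-precision
// path (sgemm + float buffers) is available for training, where fp32
// arithmetic is the field's standard; the double path is bit-faithful and
// used everywhere else. Array and weight layouts are as in ops.cpp.

#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <vector>
using namespace Rcpp;

static inline R_xlen_t fidx(int b, int c, int h, int w,
                            int B, int C, int H) {
  return (R_xlen_t)b + (R_xlen_t)B * (c + (R_xlen_t)C * (h + (R_xlen_t)H * w));
}

static void dgemm_(char ta, char tb, int m, int n, int kk, double alpha,
                   const double *a, int lda, const double *b, int ldb,
                   double beta, double *c, int ldc) {
  F77_CALL(dgemm)(&ta, &tb, &m, &n, &kk, &alpha, a, &lda, b, &ldb, &beta,
                  c, &ldc FCONE FCONE);
}

extern "C" void F77_NAME(sgemm)(const char *, const char *, const int *,
                                const int *, const int *, const float *,
                                const float *, const int *, const float *,
                                const int *, const float *, float *,
                                const int * FCLEN FCLEN);

static void sgemm_(char ta, char tb, int m, int n, int kk, float alpha,
                   const float *a, int lda, const float *b, int ldb,
                   float beta, float *c, int ldc) {
  F77_CALL(sgemm)(&ta, &tb, &m, &n, &kk, &alpha, a, &lda, b, &ldb, &beta,
                  c, &ldc FCONE FCONE);
}

// Fill the batch-interleaved patch matrix (rows b + B*(ho + Ho*wo),
// columns c*k*k + dh*k + dw) in one streamed pass: reads and writes are
// both sequential because the batch is the fastest-moving dimension on
// both sides.
template <typename T>
static void fill_patches_all(const double *px, T *M, int B, int C, int H,
                             int W, int k, int pad, int stride, int Ho,
                             int Wo) {
  const R_xlen_t nrow = (R_xlen_t)B * Ho * Wo;
  for (int c = 0; c < C; ++c)
    for (int dh = 0; dh < k; ++dh)
      for (int dw = 0; dw < k; ++dw) {
        T *mc = M + nrow * (c * k * k + dh * k + dw);
        for (int wo = 0; wo < Wo; ++wo) {
          const int ww = wo * stride - pad + dw;
          T *out = mc + (R_xlen_t)B * Ho * wo;
          if (ww < 0 || ww >= W) {
            for (R_xlen_t i = 0; i < (R_xlen_t)B * Ho; ++i) out[i] = (T)0;
            continue;
          }
          for (int ho = 0; ho < Ho; ++ho) {
            const int hh = ho * stride - pad + dh;
            T *ob = out + (R_xlen_t)B * ho;
            if (hh < 0 || hh >= H) {
              for (int b = 0; b < B; ++b) ob[b] = (T)0;
            } else {
              const double *xs = px + fidx(0, c, hh, ww, B, C, H);
              for (int b = 0; b < B; ++b) ob[b] = (T)xs[b];
            }
          }
        }
      }
}

// Scatter-add the batch-interleaved patch-matrix gradient back into dx.
template <typename T>
static void scatter_patches_all(double *pdx, const T *M, int B, int C,
                                int H, int W, int k, int pad, int stride,
                                int Ho, int Wo) {
  const R_xlen_t nrow = (R_xlen_t)B * Ho * Wo;
  for (int c = 0; c < C; ++c)
    for (int dh = 0; dh < k; ++dh)
      for (int dw = 0; dw < k; ++dw) {
        const T *mc = M + nrow * (c * k * k + dh * k + dw);
        for (int wo = 0; wo < Wo; ++wo) {
          const int ww = wo * stride - pad + dw;
          if (ww < 0 || ww >= W) continue;
          const T *in = mc + (R_xlen_t)B * Ho * wo;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hh = ho * stride - pad + dh;
            if (hh < 0 || hh >= H) continue;
            double *xs = pdx + fidx(0, c, hh, ww, B, C, H);
            const T *ib = in + (R_xlen_t)B * ho;
            for (int b = 0; b < B; ++b) xs[b] += (double)ib[b];
          }
        }
      }
}

template <typename T>
static void conv_fwd_impl(const double *px, const double *pw,
                          const double *pb, double *py, int B, int C,
                          int H, int W, int Cout, int k, int pad,
                          int stride, int Ho, int Wo) {
  const int ckk = C * k * k;
  const R_xlen_t nrow = (R_xlen_t)B * Ho * Wo;
  std::vector<T> M(nrow * ckk);
  std::vector<T> Wt((R_xlen_t)ckk * Cout);
  std::vector<T> Y(nrow * Cout);
  for (int co = 0; co < Cout; ++co)
    for (int r = 0; r < ckk; ++r)
      Wt[(R_xlen_t)r + (R_xlen_t)ckk * co] = (T)pw[co + (R_xlen_t)Cout * r];
  fill_patches_all(px, M.data(), B, C, H, W, k, pad, stride, Ho, Wo);
  if (sizeof(T) == 8)
    dgemm_('N', 'N', (int)nrow, Cout, ckk, 1.0, (const double *)M.data(),
           (int)nrow, (const double *)Wt.data(), ckk, 0.0,
           (double *)Y.data(), (int)nrow);
  else
    sgemm_('N', 'N', (int)nrow, Cout, ckk, 1.0f, (const float *)M.data(),
           (int)nrow, (const float *)Wt.data(), ckk, 0.0f,
           (float *)Y.data(), (int)nrow);
  // Y rows are b + B*(ho + Ho*wo); copy into the B,Cout,Ho,Wo array
  for (int co = 0; co < Cout; ++co) {
    const double bc = pb[co];
    const T *yc = Y.data() + nrow * co;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        double *ys = py + fidx(0, co, ho, wo, B, Cout, Ho);
        const T *yb = yc + (R_xlen_t)B * (ho + (R_xlen_t)Ho * wo);
        for (int b = 0; b < B; ++b) ys[b] = (double)yb[b] + bc;
      }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_gemm_fwd(NumericVector x, NumericMatrix Wm,
                              NumericVector bias, int B, int C, int H,
                              int W, int k, int pad, int stride,
                              bool use_float = false) {
  const int Cout = Wm.nrow();
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector y((R_xlen_t)B * Cout * Ho * Wo);
  if (use_float)
    conv_fwd_impl<float>(x.begin(), Wm.begin(), bias.begin(), y.begin(),
                         B, C, H, W, Cout, k, pad, stride, Ho, Wo);
  else
    conv_fwd_impl<double>(x.begin(), Wm.begin(), bias.begin(), y.begin(),
                          B, C, H, W, Cout, k, pad, stride, Ho, Wo);
  y.attr("dim") = IntegerVector::create(B, Cout, Ho, Wo);
  return y;
}

template <typename T>
static void conv_bwd_impl(const double *pdy, const double *px,
                          const double *pw, double *pdx, double *pdW,
                          double *pdb, int B, int C, int H, int W,
                          int Cout, int k, int pad, int stride, int Ho,
                          int Wo) {
  const int ckk = C * k * k;
  const R_xlen_t nrow = (R_xlen_t)B * Ho * Wo;
  std::vector<T> M(nrow * ckk), dM(nrow * ckk), Yb(nrow * Cout);
  std::vector<T> Wf((R_xlen_t)Cout * ckk);
  std::vector<T> dWtT((R_xlen_t)ckk * Cout);
  for (R_xlen_t i = 0; i < (R_xlen_t)Cout * ckk; ++i) Wf[i] = (T)pw[i];
  // gather dy into the interleaved matrix and accumulate db
  for (int co = 0; co < Cout; ++co) {
    double acc = 0.0;
    T *yc = Yb.data() + nrow * co;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const double *ys = pdy + fidx(0, co, ho, wo, B, Cout, Ho);
        T *yb = yc + (R_xlen_t)B * (ho + (R_xlen_t)Ho * wo);
        for (int b = 0; b < B; ++b) {
          yb[b] = (T)ys[b];
          acc += ys[b];
        }
      }
    pdb[co] = acc;
  }
  // dM = Yb * W  (nrow x ckk)
  if (sizeof(T) == 8)
    dgemm_('N', 'N', (int)nrow, ckk, Cout, 1.0, (const double *)Yb.data(),
           (int)nrow, (const double *)Wf.data(), Cout, 0.0,
           (double *)dM.data(), (int)nrow);
  else
    sgemm_('N', 'N', (int)nrow, ckk, Cout, 1.0f, (const float *)Yb.data(),
           (int)nrow, (const float *)Wf.data(), Cout, 0.0f,
           (float *)dM.data(), (int)nrow);
  scatter_patches_all(pdx, dM.data(), B, C, H, W, k, pad, stride, Ho, Wo);
  fill_patches_all(px, M.data(), B, C, H, W, k, pad, stride, Ho, Wo);
  // dW' = M' * Yb  (ckk x Cout)
  if (sizeof(T) == 8)
    dgemm_('T', 'N', ckk, Cout, (int)nrow, 1.0, (const double *)M.data(),
           (int)nrow, (const double *)Yb.data(), (int)nrow, 0.0,
           (double *)dWtT.data(), ckk);
  else
    sgemm_('T', 'N', ckk, Cout, (int)nrow, 1.0f, (const float *)M.data(),
           (int)nrow, (const float *)Yb.data(), (int)nrow, 0.0f,
           (float *)dWtT.data(), ckk);
  for (int co = 0; co < Cout; ++co)
    for (int r = 0; r < ckk; ++r)
      pdW[co + (R_xlen_t)Cout * r] =
        (double)dWtT[(R_xlen_t)r + (R_xlen_t)ckk * co];
}

// [[Rcpp::export]]
List conv2d_gemm_bwd(NumericVector dy, NumericVector x, NumericMatrix Wm,
                     int B, int C, int H, int W, int k, int pad,
                     int stride, bool use_float = false) {
  const int Cout = Wm.nrow();
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector dx((R_xlen_t)B * C * H * W);
  NumericMatrix dW(Cout, C * k * k);
  NumericVector db(Cout);
  if (use_float)
    conv_bwd_impl<float>(dy.begin(), x.begin(), Wm.begin(), dx.begin(),
                         dW.begin(), db.begin(), B, C, H, W, Cout, k, pad,
                         stride, Ho, Wo);
  else
    conv_bwd_impl<double>(dy.begin(), x.begin(), Wm.begin(), dx.begin(),
                          dW.begin(), db.begin(), B, C, H, W, Cout, k,
                          pad, stride, Ho, Wo);
  dx.attr("dim") = IntegerVector::create(B, C, H, W);
  return List::create(_["dx"] = dx, _["W"] = dW, _["b"] = db);
}

// Transposed convolution (kernel k, stride s, no padding), weight layout
// (Cout*k*k) x Cin as in tconv2d_init. Double precision only: these
// layers run at coarse resolutions where speed is not a concern.

// [[Rcpp::export]]
NumericVector tconv2d_gemm_fwd(NumericVector x, NumericMatrix Wm,
                               NumericVector bias, int B, int C, int H,
                               int W, int Cout, int k, int stride) {
  const int Ho = H * stride, Wo = W * stride;
  const int hw = H * W, wrows = Cout * k * k;
  NumericVector y((R_xlen_t)B * Cout * Ho * Wo);
  double *py = y.begin();
  const double *px = x.begin();
  const double *pw = Wm.begin();             // wrows x C
  const R_xlen_t xblk = (R_xlen_t)hw * C, yblk = (R_xlen_t)hw * wrows;
  std::vector<double> Xb((R_xlen_t)B * xblk), Y((R_xlen_t)B * yblk);
  for (int c = 0; c < C; ++c)
    for (int w0 = 0; w0 < W; ++w0)
      for (int h0 = 0; h0 < H; ++h0) {
        const double *xs = px + fidx(0, c, h0, w0, B, C, H);
        const R_xlen_t off = (R_xlen_t)c * hw + (R_xlen_t)w0 * H + h0;
        for (int b = 0; b < B; ++b) Xb[(R_xlen_t)b * xblk + off] = xs[b];
      }
  for (int b = 0; b < B; ++b)
    dgemm_('N', 'T', hw, wrows, C, 1.0, Xb.data() + (R_xlen_t)b * xblk,
           hw, pw, wrows, 0.0, Y.data() + (R_xlen_t)b * yblk, hw);
  for (int co = 0; co < Cout; ++co) {
    const double bc = bias[co];
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        double *ys = py + fidx(0, co, ho, wo, B, Cout, Ho);
        for (int b = 0; b < B; ++b) ys[b] = bc;
      }
    for (int dh = 0; dh < k; ++dh)
      for (int dw = 0; dw < k; ++dw) {
        const R_xlen_t coloff =
          (R_xlen_t)(co * k * k + dh * k + dw) * hw;
        for (int w0 = 0; w0 < W; ++w0) {
          const int wo = w0 * stride + dw;
          if (wo >= Wo) continue;
          for (int h0 = 0; h0 < H; ++h0) {
            const int ho = h0 * stride + dh;
            if (ho >= Ho) continue;
            double *ys = py + fidx(0, co, ho, wo, B, Cout, Ho);
            const R_xlen_t off = coloff + (R_xlen_t)w0 * H + h0;
            for (int b = 0; b < B; ++b)
              ys[b] += Y[(R_xlen_t)b * yblk + off];
          }
        }
      }
  }
  y.attr("dim") = IntegerVector::create(B, Cout, Ho, Wo);
  return y;
}

// [[Rcpp::export]]
List tconv2d_gemm_bwd(NumericVector dy, NumericVector x, NumericMatrix Wm,
                      int B, int C, int H, int W, int Cout, int k,
                      int stride) {
  const int Ho = H * stride, Wo = W * stride;
  const int hw = H * W, wrows = Cout * k * k;
  NumericVector dx((R_xlen_t)B * C * H * W);
  NumericMatrix dW(wrows, C);
  NumericVector db(Cout);
  double *pdx = dx.begin();
  const double *pdy = dy.begin();
  const double *px = x.begin();
  const double *pw = Wm.begin();
  const R_xlen_t xblk = (R_xlen_t)hw * C, mblk = (R_xlen_t)hw * wrows;
  std::vector<double> dM((R_xlen_t)B * mblk, 0.0),
    Xb((R_xlen_t)B * xblk), dXb((R_xlen_t)B * xblk),
    dWacc((R_xlen_t)wrows * C, 0.0);
  for (int co = 0; co < Cout; ++co) {
    double acc = 0.0;
    for (int dh = 0; dh < k; ++dh)
      for (int dw = 0; dw < k; ++dw) {
        const R_xlen_t coloff = (R_xlen_t)(co * k * k + dh * k + dw) * hw;
        for (int w0 = 0; w0 < W; ++w0) {
          const int wo = w0 * stride + dw;
          for (int h0 = 0; h0 < H; ++h0) {
            const int ho = h0 * stride + dh;
            const R_xlen_t off = coloff + (R_xlen_t)w0 * H + h0;
            if (ho < Ho && wo < Wo) {
              const double *ys = pdy + fidx(0, co, ho, wo, B, Cout, Ho);
              for (int b = 0; b < B; ++b)
                dM[(R_xlen_t)b * mblk + off] = ys[b];
            } else {
              for (int b = 0; b < B; ++b)
                dM[(R_xlen_t)b * mblk + off] = 0.0;
            }
          }
        }
      }
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const double *ys = pdy + fidx(0, co, ho, wo, B, Cout, Ho);
        for (int b = 0; b < B; ++b) acc += ys[b];
      }
    db[co] = acc;
  }
  for (int c = 0; c < C; ++c)
    for (int w0 = 0; w0 < W; ++w0)
      for (int h0 = 0; h0 < H; ++h0) {
        const double *xs = px + fidx(0, c, h0, w0, B, C, H);
        const R_xlen_t off = (R_xlen_t)c * hw + (R_xlen_t)w0 * H + h0;
        for (int b = 0; b < B; ++b) Xb[(R_xlen_t)b * xblk + off] = xs[b];
      }
  for (int b = 0; b < B; ++b) {
    dgemm_('N', 'N', hw, C, wrows, 1.0, dM.data() + (R_xlen_t)b * mblk,
           hw, pw, wrows, 0.0, dXb.data() + (R_xlen_t)b * xblk, hw);
    dgemm_('T', 'N', wrows, C, hw, 1.0, dM.data() + (R_xlen_t)b * mblk,
           hw, Xb.data() + (R_xlen_t)b * xblk, hw, 1.0, dWacc.data(),
           wrows);
  }
  for (int c = 0; c < C; ++c)
    for (int w0 = 0; w0 < W; ++w0)
      for (int h0 = 0; h0 < H; ++h0) {
        double *xs = pdx + fidx(0, c, h0, w0, B, C, H);
        const R_xlen_t off = (R_xlen_t)c * hw + (R_xlen_t)w0 * H + h0;
        for (int b = 0; b < B; ++b) xs[b] = dXb[(R_xlen_t)b * xblk + off];
      }
  for (R_xlen_t i = 0; i < (R_xlen_t)wrows * C; ++i) dW[i] = dWacc[i];
  dx.attr("dim") = IntegerVector::create(B, C, H, W);
  return List::create(_["dx"] = dx, _["W"] = dW, _["b"] = db);
}

// ---- elementwise helpers ----------------------------------------------------

// [[Rcpp::export]]
NumericVector relu_fwd_cpp(NumericVector x) {
  NumericVector y = clone(x);
  double *p = y.begin();
  for (R_xlen_t i = 0; i < y.size(); ++i)
    if (p[i] < 0) p[i] = 0;
  return y;
}

// dy * (pre > 0)
// [[Rcpp::export]]
NumericVector relu_bwd_cpp(NumericVector dy, NumericVector pre) {
  NumericVector dx = clone(dy);
  double *p = dx.begin();
  const double *q = pre.begin();
  for (R_xlen_t i = 0; i < dx.size(); ++i)
    if (q[i] <= 0) p[i] = 0;
  return dx;
}
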