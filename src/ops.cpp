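#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are R arrays with dim c(B, C, H, W) (column-major, batch
// fastest). Convolution weights are matrices of dim c(Cout, Cin*k*k) with
// row index for input channel c, kernel offset (dh, dw), dh/dw in 1..k:
//   (c-1)*k*k + (dh-1)*k + (dw-1) + 1.
// im2col column index for batch b and output pixel (ho, wo):
//   (b-1)*Ho*Wo + (wo-1)*Ho + (ho-1) + 1   (spatial column-major, h fastest)

static inline R_xlen_t feat_idx(int b, int c, int h, int w,
                                int B, int C, int H) {
  return (R_xlen_t)b + (R_xlen_t)B * (c + (R_xlen_t)C * (h + (R_xlen_t)H * w));
}

// [[Rcpp::export]]
NumericMatrix im2col_bchw(NumericVector x, int B, int C, int H, int W,
                          int k, int pad, int stride) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericMatrix out(C * k * k, (R_xlen_t)B * Ho * Wo);
  double *po = out.begin();
  const double *px = x.begin();
  const R_xlen_t nrow = (R_xlen_t)C * k * k;
  for (int b = 0; b < B; ++b) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const R_xlen_t col = (R_xlen_t)b * Ho * Wo + (R_xlen_t)wo * Ho + ho;
        double *pc = po + col * nrow;
        for (int c = 0; c < C; ++c) {
          for (int dh = 0; dh < k; ++dh) {
            const int h = ho * stride - pad + dh;
            for (int dw = 0; dw < k; ++dw) {
              const int w = wo * stride - pad + dw;
              double v = 0.0;
              if (h >= 0 && h < H && w >= 0 && w < W)
                v = px[feat_idx(b, c, h, w, B, C, H)];
              pc[(R_xlen_t)c * k * k + (R_xlen_t)dh * k + dw] = v;
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col: scatter-add columns back into a B*C*H*W array.
// [[Rcpp::export]]
NumericVector col2im_bchw(NumericMatrix cols, int B, int C, int H, int W,
                          int k, int pad, int stride) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector x((R_xlen_t)B * C * H * W);
  double *px = x.begin();
  const double *pc0 = cols.begin();
  const R_xlen_t nrow = (R_xlen_t)C * k * k;
  for (int b = 0; b < B; ++b) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const R_xlen_t col = (R_xlen_t)b * Ho * Wo + (R_xlen_t)wo * Ho + ho;
        const double *pc = pc0 + col * nrow;
        for (int c = 0; c < C; ++c) {
          for (int dh = 0; dh < k; ++dh) {
            const int h = ho * stride - pad + dh;
            if (h < 0 || h >= H) continue;
            for (int dw = 0; dw < k; ++dw) {
              const int w = wo * stride - pad + dw;
              if (w < 0 || w >= W) continue;
              px[feat_idx(b, c, h, w, B, C, H)] +=
                pc[(R_xlen_t)c * k * k + (R_xlen_t)dh * k + dw];
            }
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(B, C, H, W);
  return x;
}

// Reshape a C x (B*H*W) matrix (columns ordered as in im2col with k = 1)
// into a B,C,H,W array.
// [[Rcpp::export]]
NumericVector mat2feat_bchw(NumericMatrix m, int B, int C, int H, int W) {
  NumericVector x((R_xlen_t)B * C * H * W);
  double *px = x.begin();
  const double *pm = m.begin();
  for (int b = 0; b < B; ++b)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        const R_xlen_t col = (R_xlen_t)b * H * W + (R_xlen_t)w * H + h;
        for (int c = 0; c < C; ++c)
          px[feat_idx(b, c, h, w, B, C, H)] = pm[col * C + c];
      }
  x.attr("dim") = IntegerVector::create(B, C, H, W);
  return x;
}

// Inverse of mat2feat_bchw.
// [[Rcpp::export]]
NumericMatrix feat2mat_bchw(NumericVector x, int B, int C, int H, int W) {
  NumericMatrix m(C, (R_xlen_t)B * H * W);
  double *pm = m.begin();
  const double *px = x.begin();
  for (int b = 0; b < B; ++b)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        const R_xlen_t col = (R_xlen_t)b * H * W + (R_xlen_t)w * H + h;
        for (int c = 0; c < C; ++c)
          pm[col * C + c] = px[feat_idx(b, c, h, w, B, C, H)];
      }
  return m;
}

// 2x2 max pooling with stride 2; H and W must be even. Returns the pooled
// array and the 1-based flat indices of the maxima for the backward pass.
// [[Rcpp::export]]
List maxpool2_fwd(NumericVector x, int B, int C, int H, int W) {
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)B * C * Ho * Wo);
  IntegerVector arg((R_xlen_t)B * C * Ho * Wo);
  const double *px = x.begin();
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = R_NegInf; R_xlen_t bi = 0;
          for (int dh = 0; dh < 2; ++dh)
            for (int dw = 0; dw < 2; ++dw) {
              const R_xlen_t ii =
                feat_idx(b, c, 2 * ho + dh, 2 * wo + dw, B, C, H);
              if (px[ii] > best) { best = px[ii]; bi = ii; }
            }
          const R_xlen_t oi = feat_idx(b, c, ho, wo, B, C, Ho);
          y[oi] = best;
          arg[oi] = (int)(bi + 1);
        }
  y.attr("dim") = IntegerVector::create(B, C, Ho, Wo);
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd(NumericVector dy, IntegerVector argmax,
                           int B, int C, int H, int W) {
  NumericVector dx((R_xlen_t)B * C * H * W);
  const double *pd = dy.begin();
  for (R_xlen_t i = 0; i < dy.size(); ++i)
    dx[(R_xlen_t)argmax[i] - 1] += pd[i];
  dx.attr("dim") = IntegerVector::create(B, C, H, W);
  return dx;
}
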