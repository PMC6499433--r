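#include <Rcpp.h>
using namespace Rcpp;

// Patch extraction (im2col) and its adjoint (col2im) for 4-D arrays in R's
// column-major (N, H, W, C) layout. Convolutions are expressed as
// im2col %*% kernel-matrix so the heavy lifting stays in BLAS; these two
// routines are the only compiled pieces of the package.
//
// Rows of the patch matrix are ordered (n, oh, ow) with n fastest, matching
// the layout of an R array dim = c(N, Ho, Wo, ...), so the matmul result can
// be reinterpreted as an (N, Ho, Wo, Cout) array without copying.
// Columns are ordered (kh, kw, c) with kh fastest, matching
// matrix(w, kh*kw*Cin, Cout) for a kernel array dim = c(kh, kw, Cin, Cout).

// [[Rcpp::export]]
NumericMatrix im2col_nhwc(NumericVector x, int kh, int kw, int stride,
                          int pad) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("x must be a 4-d array (N, H, W, C)");
  const int N = d[0], H = d[1], W = d[2], C = d[3];
  const int Hp = H + 2 * pad, Wp = W + 2 * pad;
  if (kh > Hp || kw > Wp) stop("kernel larger than (padded) image");
  const int Ho = (Hp - kh) / stride + 1;
  const int Wo = (Wp - kw) / stride + 1;
  const R_xlen_t nrow = (R_xlen_t)N * Ho * Wo;
  NumericMatrix out(nrow, kh * kw * C);
  const double *px = x.begin();
  double *po = out.begin();
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const R_xlen_t col = ki + (R_xlen_t)kh * (kj + (R_xlen_t)kw * c);
        double *pcol = po + col * nrow;
        for (int ow = 0; ow < Wo; ++ow) {
          const int j = ow * stride + kj - pad;
          for (int oh = 0; oh < Ho; ++oh) {
            const int i = oh * stride + ki - pad;
            double *dst = pcol + (R_xlen_t)N * (oh + (R_xlen_t)Ho * ow);
            if (i < 0 || i >= H || j < 0 || j >= W) {
              for (int n = 0; n < N; ++n) dst[n] = 0.0;
            } else {
              const double *src =
                  px + (R_xlen_t)N * (i + (R_xlen_t)H * (j + (R_xlen_t)W * c));
              for (int n = 0; n < N; ++n) dst[n] = src[n];
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col_nhwc: scatter-adds patch-matrix gradients back onto the
// input grid. `cols` must have the row/column ordering produced above.
// [[Rcpp::export]]
NumericVector col2im_nhwc(NumericMatrix cols, int N, int H, int W, int C,
                          int kh, int kw, int stride, int pad) {
  const int Hp = H + 2 * pad, Wp = W + 2 * pad;
  const int Ho = (Hp - kh) / stride + 1;
  const int Wo = (Wp - kw) / stride + 1;
  if (cols.nrow() != (R_xlen_t)N * Ho * Wo || cols.ncol() != kh * kw * C)
    stop("cols has wrong shape for the given geometry");
  NumericVector x((R_xlen_t)N * H * W * C);
  x.attr("dim") = IntegerVector::create(N, H, W, C);
  const double *pc = cols.begin();
  double *px = x.begin();
  const R_xlen_t nrow = cols.nrow();
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const R_xlen_t col = ki + (R_xlen_t)kh * (kj + (R_xlen_t)kw * c);
        const double *pcol = pc + col * nrow;
        for (int ow = 0; ow < Wo; ++ow) {
          const int j = ow * stride + kj - pad;
          if (j < 0 || j >= W) continue;
          for (int oh = 0; oh < Ho; ++oh) {
            const int i = oh * stride + ki - pad;
            if (i < 0 || i >= H) continue;
            const double *src = pcol + (R_xlen_t)N * (oh + (R_xlen_t)Ho * ow);
            double *dst =
                px + (R_xlen_t)N * (i + (R_xlen_t)H * (j + (R_xlen_t)W * c));
            for (int n = 0; n < N; ++n) dst[n] += src[n];
          }
        }
      }
    }
  }
  return x;
}
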