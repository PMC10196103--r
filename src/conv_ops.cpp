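#include <Rcpp.h>
using namespace Rcpp;

// 3x3 same-padding im2col for column-major arrays of dim (H, W, C, N).
// Output matrix: rows indexed by (h + H*w + H*W*n), columns by
// (kh + 3*kw + 9*c), so a convolution is out %*% Wmat with Wmat of dim
// (9*C, Cout).
// [[Rcpp::export]]
NumericMatrix im2col3_cpp(NumericVector x, int H, int W, int C, int N) {
  const int HW = H * W;
  NumericMatrix out(HW * N, 9 * C);
  const double *px = x.begin();
  double *po = out.begin();
  const R_xlen_t nrow = (R_xlen_t)HW * N;
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < 3; ++kw) {
      for (int kh = 0; kh < 3; ++kh) {
        const int q = kh + 3 * kw + 9 * c;
        double *col = po + (R_xlen_t)q * nrow;
        for (int n = 0; n < N; ++n) {
          const double *plane = px + ((R_xlen_t)n * C + c) * HW;
          double *dst = col + (R_xlen_t)n * HW;
          for (int w = 0; w < W; ++w) {
            const int ws = w + kw - 1;
            double *d = dst + (R_xlen_t)w * H;
            if (ws < 0 || ws >= W) {
              for (int h = 0; h < H; ++h) d[h] = 0.0;
            } else {
              const double *s = plane + (R_xlen_t)ws * H;
              const int off = kh - 1;
              for (int h = 0; h < H; ++h) {
                const int hs = h + off;
                d[h] = (hs < 0 || hs >= H) ? 0.0 : s[hs];
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// Reorder a (H*W*N) x C matrix (rows: h + H*w + H*W*n) into an array of
// dim (H, W, C, N).
// [[Rcpp::export]]
NumericVector mat2arr_cpp(NumericMatrix m, int H, int W, int C, int N) {
  const R_xlen_t HW = (R_xlen_t)H * W;
  NumericVector x(HW * C * N);
  double *px = x.begin();
  const double *pm = m.begin();
  const R_xlen_t nrow = HW * N;
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n)
      std::copy(pm + c * nrow + n * HW, pm + c * nrow + (n + 1) * HW,
                px + ((R_xlen_t)n * C + c) * HW);
  return x;
}

// Inverse of mat2arr_cpp: array (H, W, C, N) to (H*W*N) x C matrix.
// [[Rcpp::export]]
NumericMatrix arr2mat_cpp(NumericVector x, int H, int W, int C, int N) {
  const R_xlen_t HW = (R_xlen_t)H * W;
  NumericMatrix m(HW * N, C);
  double *pm = m.begin();
  const double *px = x.begin();
  const R_xlen_t nrow = HW * N;
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n)
      std::copy(px + ((R_xlen_t)n * C + c) * HW,
                px + ((R_xlen_t)n * C + c + 1) * HW,
                pm + c * nrow + n * HW);
  return m;
}

// Adjoint of im2col3_cpp: scatter-add a (H*W*N) x (9*C) matrix back to an
// array of dim (H, W, C, N).
// [[Rcpp::export]]
NumericVector col2im3_cpp(NumericMatrix m, int H, int W, int C, int N) {
  const int HW = H * W;
  NumericVector x((R_xlen_t)HW * C * N);
  double *px = x.begin();
  const double *pm = m.begin();
  const R_xlen_t nrow = (R_xlen_t)HW * N;
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < 3; ++kw) {
      for (int kh = 0; kh < 3; ++kh) {
        const int q = kh + 3 * kw + 9 * c;
        const double *col = pm + (R_xlen_t)q * nrow;
        for (int n = 0; n < N; ++n) {
          double *plane = px + ((R_xlen_t)n * C + c) * HW;
          const double *src = col + (R_xlen_t)n * HW;
          for (int w = 0; w < W; ++w) {
            const int ws = w + kw - 1;
            if (ws < 0 || ws >= W) continue;
            const double *s = src + (R_xlen_t)w * H;
            double *d = plane + (R_xlen_t)ws * H;
            const int off = kh - 1;
            for (int h = 0; h < H; ++h) {
              const int hs = h + off;
              if (hs >= 0 && hs < H) d[hs] += s[h];
            }
          }
        }
      }
    }
  }
  return x;
}
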