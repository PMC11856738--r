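#include <Rcpp.h>
using namespace Rcpp;

// Feature arrays use an (H, W, N, C) column-major layout so that flattening
// gives an (H*W*N) x C matrix whose columns are channels; convolutions then
// reduce to one GEMM against a (kh*kw*C) x Cout weight matrix.
//
// im2col row index: r = ho + Ho*(wo + Wo*n); column index: dh + kh*(dw + kw*c).
// Out-of-grid taps read as zero (zero padding).

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int N, int C,
                         int kh, int kw, int stride, int pad) {
  const int Ho = out_size(H, kh, stride, pad);
  const int Wo = out_size(W, kw, stride, pad);
  const R_xlen_t R = (R_xlen_t)N * Ho * Wo;
  NumericMatrix out(R, kh * kw * C);
  double* po = out.begin();
  const double* px = x.begin();
  for (int c = 0; c < C; ++c) {
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const int col = dh + kh * (dw + kw * c);
        double* pcol = po + (R_xlen_t)col * R;
        for (int n = 0; n < N; ++n) {
          const double* pxc = px + ((R_xlen_t)c * N + n) * H * W;
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride - pad + dw;
            double* prow = pcol + (R_xlen_t)(wo + (R_xlen_t)Wo * n) * Ho;
            if (wi < 0 || wi >= W) {
              for (int ho = 0; ho < Ho; ++ho) prow[ho] = 0.0;
            } else {
              const double* pxw = pxc + (R_xlen_t)wi * H;
              for (int ho = 0; ho < Ho; ++ho) {
                const int hi = ho * stride - pad + dh;
                prow[ho] = (hi >= 0 && hi < H) ? pxw[hi] : 0.0;
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col: scatter-adds patch columns back onto the input grid.
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int N, int C,
                         int kh, int kw, int stride, int pad) {
  const int Ho = out_size(H, kh, stride, pad);
  const int Wo = out_size(W, kw, stride, pad);
  const R_xlen_t R = (R_xlen_t)N * Ho * Wo;
  NumericVector x((R_xlen_t)H * W * N * C);
  double* px = x.begin();
  const double* pc = cols.begin();
  for (int c = 0; c < C; ++c) {
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const int col = dh + kh * (dw + kw * c);
        const double* pcol = pc + (R_xlen_t)col * R;
        for (int n = 0; n < N; ++n) {
          double* pxc = px + ((R_xlen_t)c * N + n) * H * W;
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride - pad + dw;
            if (wi < 0 || wi >= W) continue;
            const double* prow = pcol + (R_xlen_t)(wo + (R_xlen_t)Wo * n) * Ho;
            double* pxw = pxc + (R_xlen_t)wi * H;
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * stride - pad + dh;
              if (hi >= 0 && hi < H) pxw[hi] += prow[ho];
            }
          }
        }
      }
    }
  }
  return x;
}
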