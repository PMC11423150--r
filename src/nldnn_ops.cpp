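// Hot-path kernels for the 1-D convolution layers: im2col gather and
// col2im scatter-add with implicit 'same' zero padding. The GEMM itself
// stays in R (BLAS).

#include <Rcpp.h>
using namespace Rcpp;

// X: flat (C, L, B) array; returns (C*k, L*B) matrix, rows ordered
// channel-fastest within kernel offset (row = c + j*C).
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector X, int C, int L, int B, int k) {
  int pl = (k - 1) / 2;
  NumericMatrix M(C * k, L * B);
  const double* x = X.begin();
  double* m = M.begin();
  int rows = C * k;
  for (int b = 0; b < B; ++b) {
    const double* xb = x + (R_xlen_t)b * C * L;
    for (int l = 0; l < L; ++l) {
      double* col = m + (R_xlen_t)(b * L + l) * rows;
      for (int j = 0; j < k; ++j) {
        int src = l + j - pl;              // source position along length
        double* dst = col + j * C;
        if (src < 0 || src >= L) {
          for (int c = 0; c < C; ++c) dst[c] = 0.0;
        } else {
          const double* s = xb + (R_xlen_t)src * C;
          for (int c = 0; c < C; ++c) dst[c] = s[c];
        }
      }
    }
  }
  return M;
}

// dM: (C*k, L*B); returns flat (C, L, B) gradient array.
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix dM, int C, int L, int B, int k) {
  int pl = (k - 1) / 2;
  NumericVector dX((R_xlen_t)C * L * B);
  double* dx = dX.begin();
  const double* m = dM.begin();
  int rows = C * k;
  for (int b = 0; b < B; ++b) {
    double* dxb = dx + (R_xlen_t)b * C * L;
    for (int l = 0; l < L; ++l) {
      const double* col = m + (R_xlen_t)(b * L + l) * rows;
      for (int j = 0; j < k; ++j) {
        int src = l + j - pl;
        if (src < 0 || src >= L) continue;
        double* d = dxb + (R_xlen_t)src * C;
        const double* s = col + j * C;
        for (int c = 0; c < C; ++c) d[c] += s[c];
      }
    }
  }
  return dX;
}
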