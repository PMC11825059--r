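#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Unrolls a batch of 1D multichannel series (layout C x l x N,
// column-major) into the im2col matrix (C*k) x (l*N) for a stride-1,
// same-padding convolution with kernel width k. Column (n*l + t) holds
// the k receptive-field slices of case n centred at time t; positions
// outside [0, l) are zero.

// [[Rcpp::export]]
NumericMatrix im2col1d(NumericVector x, int C, int l, int N, int k) {
  int pl = (k - 1) / 2;
  NumericMatrix out(C * k, l * N);
  double* po = out.begin();
  double* px = x.begin();
  for (int n = 0; n < N; ++n) {
    for (int t = 0; t < l; ++t) {
      double* col = po + (size_t)(n * l + t) * C * k;
      for (int j = 0; j < k; ++j) {
        int ts = t + j - pl;
        if (ts >= 0 && ts < l) {
          std::memcpy(col + (size_t)j * C, px + (size_t)(n * l + ts) * C,
                      C * sizeof(double));
        } else {
          std::memset(col + (size_t)j * C, 0, C * sizeof(double));
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col1d: scatter-adds the (C*k) x (l*N) gradient back to
// the C x (l*N) input layout.

// [[Rcpp::export]]
NumericMatrix col2im1d(NumericMatrix dXcol, int C, int l, int N, int k) {
  int pl = (k - 1) / 2;
  NumericMatrix out(C, l * N);
  double* po = out.begin();
  double* pc = dXcol.begin();
  for (int n = 0; n < N; ++n) {
    for (int t = 0; t < l; ++t) {
      double* col = pc + (size_t)(n * l + t) * C * k;
      for (int j = 0; j < k; ++j) {
        int ts = t + j - pl;
        if (ts >= 0 && ts < l) {
          double* dst = po + (size_t)(n * l + ts) * C;
          double* src = col + (size_t)j * C;
          for (int c0 = 0; c0 < C; ++c0) dst[c0] += src[c0];
        }
      }
    }
  }
  return out;
}
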