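// Minimal convolution kernels for the 50-layer residual feature extractor:
// im2col + BLAS matmul convolution and 2-D max pooling on H x W x C arrays.
// 1x1 convolutions skip im2col and multiply the (pixels x channels) view of
// the input directly.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// x: H x W x C input; w: (kh*kw*C) x Cout weight matrix whose rows are
// ordered (c * kh + ki) * kw + kj; b: Cout bias.
// [[Rcpp::export]]
arma::cube conv2d_forward(const arma::cube& x, const arma::mat& w,
                          const arma::vec& b, int kh, int kw,
                          int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  if ((int)w.n_rows != kh * kw * C)
    Rcpp::stop("weight rows (%d) != kh*kw*C (%d)", (int)w.n_rows, kh * kw * C);
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const size_t P = (size_t)Ho * Wo;
  mat out;
  if (kh == 1 && kw == 1 && pad == 0 && stride == 1) {
    const mat xm(const_cast<double*>(x.memptr()), (size_t)H * W, C, false, true);
    out = xm * w;                               // P x Cout
  } else {
    mat cols(P, (size_t)kh * kw * C, fill::zeros);
    for (int c = 0; c < C; ++c) {
      for (int ki = 0; ki < kh; ++ki) {
        for (int kj = 0; kj < kw; ++kj) {
          const size_t col = (size_t)(c * kh + ki) * kw + kj;
          double* dst = cols.colptr(col);
          for (int wo = 0; wo < Wo; ++wo) {
            const int jin = wo * stride - pad + kj;
            if (jin < 0 || jin >= W) continue;
            const double* src = x.slice_colptr(c, jin);
            double* d2 = dst + (size_t)wo * Ho;
            for (int ho = 0; ho < Ho; ++ho) {
              const int iin = ho * stride - pad + ki;
              if (iin >= 0 && iin < H) d2[ho] = src[iin];
            }
          }
        }
      }
    }
    out = cols * w;                             // P x Cout
  }
  out.each_row() += b.t();
  cube res(Ho, Wo, w.n_cols);
  std::memcpy(res.memptr(), out.memptr(), sizeof(double) * P * w.n_cols);
  return res;
}

// [[Rcpp::export]]
arma::cube maxpool2d(const arma::cube& x, int k, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  cube res(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double m = -datum::inf;
        for (int kj = 0; kj < k; ++kj) {
          const int jin = wo * stride - pad + kj;
          if (jin < 0 || jin >= W) continue;
          const double* src = x.slice_colptr(c, jin);
          for (int ki = 0; ki < k; ++ki) {
            const int iin = ho * stride - pad + ki;
            if (iin >= 0 && iin < H && src[iin] > m) m = src[iin];
          }
        }
        res.at(ho, wo, c) = m;
      }
    }
  }
  return res;
}
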