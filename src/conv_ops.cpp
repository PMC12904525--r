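// im2col-based 2-D convolution kernels (forward, input-gradient,
// weight-gradient) plus depthwise variants. Tensors are H x W x C arma
// cubes; weights are (kh*kw*Cin) x Cout matrices with row ordering
// ki + kj*kh + c*kh*kw (all 0-based). Zero padding, square strides.
// The forward pass returns its im2col matrix so the backward pass reuses
// it for the weight gradient.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

static mat im2col(const cube& x, int kh, int kw, int stride, int pad,
                  int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat out(Ho * Wo, kh * kw * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.slice_memptr(c);
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int col = c * kh * kw + kj * kh + ki;
        double* op = out.colptr(col);
        // valid ho range: 0 <= ho*stride + ki - pad <= H-1
        int ho_lo = std::max(0, (pad - ki + stride - 1) / stride);
        int ho_hi = std::min(Ho - 1, (H - 1 - ki + pad) / stride);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride + kj - pad;
          if (wi < 0 || wi >= W) continue;
          const double* src = xc + (size_t)wi * H;
          double* dst = op + (size_t)wo * Ho;
          if (stride == 1) {
            const int h0 = ho_lo + ki - pad;
            std::copy(src + h0, src + h0 + (ho_hi - ho_lo + 1),
                      dst + ho_lo);
          } else {
            for (int ho = ho_lo; ho <= ho_hi; ++ho) {
              dst[ho] = src[ho * stride + ki - pad];
            }
          }
        }
      }
    }
  }
  return out;
}

static cube col2im(const mat& cols, int H, int W, int C, int kh, int kw,
                   int stride, int pad, int Ho, int Wo) {
  cube dx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* xc = dx.slice_memptr(c);
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int col = c * kh * kw + kj * kh + ki;
        const double* ip = cols.colptr(col);
        int ho_lo = std::max(0, (pad - ki + stride - 1) / stride);
        int ho_hi = std::min(Ho - 1, (H - 1 - ki + pad) / stride);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride + kj - pad;
          if (wi < 0 || wi >= W) continue;
          double* dst = xc + (size_t)wi * H;
          const double* src = ip + (size_t)wo * Ho;
          for (int ho = ho_lo; ho <= ho_hi; ++ho) {
            dst[ho * stride + ki - pad] += src[ho];
          }
        }
      }
    }
  }
  return dx;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv2d_fwd(const arma::cube& x, const arma::mat& w,
                          const arma::vec& b, int kh, int kw, int stride,
                          int pad) {
  const int Ho = out_size(x.n_rows, kh, stride, pad);
  const int Wo = out_size(x.n_cols, kw, stride, pad);
  const int Cout = w.n_cols;
  mat xc = im2col(x, kh, kw, stride, pad, Ho, Wo);
  mat y = xc * w;
  y.each_row() += b.t();
  cube out(Ho, Wo, Cout);
  for (int c = 0; c < Cout; ++c) {
    std::copy(y.colptr(c), y.colptr(c) + Ho * Wo, out.slice_memptr(c));
  }
  return Rcpp::List::create(Rcpp::Named("y") = out,
                            Rcpp::Named("xc") = xc);
}

// [[Rcpp::export]]
Rcpp::List cpp_conv2d_bwd(const arma::mat& xc, const arma::mat& w,
                          const arma::cube& dy, int H, int W, int C,
                          int kh, int kw, int stride, int pad) {
  const int Ho = dy.n_rows, Wo = dy.n_cols, Cout = dy.n_slices;
  mat dymat(Ho * Wo, Cout);
  for (int c = 0; c < Cout; ++c) {
    std::copy(dy.slice_memptr(c), dy.slice_memptr(c) + Ho * Wo,
              dymat.colptr(c));
  }
  mat dw = xc.t() * dymat;
  vec db = sum(dymat, 0).t();
  cube dx = col2im(dymat * w.t(), H, W, C, kh, kw, stride, pad, Ho, Wo);
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}

// Depthwise convolution, stride 1; w is (kh*kw) x C.
// [[Rcpp::export]]
arma::cube cpp_dwconv2d_fwd(const arma::cube& x, const arma::mat& w,
                            const arma::vec& b, int kh, int kw, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = out_size(H, kh, 1, pad), Wo = out_size(W, kw, 1, pad);
  cube y(Ho, Wo, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& xc = x.slice(c);
    mat& yc = y.slice(c);
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const double wv = w(ki + kj * kh, c);
        if (wv == 0) continue;
        const int ho_lo = std::max(0, pad - ki);
        const int ho_hi = std::min(Ho - 1, H - 1 - ki + pad);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo + kj - pad;
          if (wi < 0 || wi >= W) continue;
          const double* src = xc.colptr(wi);
          double* dst = yc.colptr(wo);
          for (int ho = ho_lo; ho <= ho_hi; ++ho) {
            dst[ho] += wv * src[ho + ki - pad];
          }
        }
      }
    }
    yc += b(c);
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List cpp_dwconv2d_bwd(const arma::cube& x, const arma::mat& w,
                            const arma::cube& dy, int kh, int kw, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = dy.n_rows, Wo = dy.n_cols;
  cube dx(H, W, C, fill::zeros);
  mat dw(kh * kw, C, fill::zeros);
  vec db(C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& xc = x.slice(c);
    const mat& dyc = dy.slice(c);
    mat& dxc = dx.slice(c);
    db(c) = accu(dyc);
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const double wv = w(ki + kj * kh, c);
        double acc = 0.0;
        const int ho_lo = std::max(0, pad - ki);
        const int ho_hi = std::min(Ho - 1, H - 1 - ki + pad);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo + kj - pad;
          if (wi < 0 || wi >= W) continue;
          const double* src = xc.colptr(wi);
          const double* dys = dyc.colptr(wo);
          double* dxp = dxc.colptr(wi);
          for (int ho = ho_lo; ho <= ho_hi; ++ho) {
            acc += dys[ho] * src[ho + ki - pad];
            dxp[ho + ki - pad] += dys[ho] * wv;
          }
        }
        dw(ki + kj * kh, c) = acc;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}
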