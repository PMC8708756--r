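// 2D convolution primitives (im2col + GEMM) used by the translation
// networks. Tensors are R arrays of dim (H, W, C), column-major; weights are
// matrices of dim (kh*kw*cin) x cout with patch index q = r + kh*s +
// kh*kw*c (row offset r, column offset s, input channel c).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat im2col(const arma::cube& x, int kh, int kw, int stride,
                        int pad, int oh, int ow) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat cols(oh * ow, kh * kw * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const arma::mat& xc = x.slice(c);
    for (int s = 0; s < kw; ++s) {
      for (int r = 0; r < kh; ++r) {
        const int q = r + kh * s + kh * kw * c;
        double* colq = cols.colptr(q);
        for (int ox = 0; ox < ow; ++ox) {
          const int ix = ox * stride - pad + s;
          if (ix < 0 || ix >= W) continue;
          const double* xcol = xc.colptr(ix);
          const int base = oh * ox;
          for (int oy = 0; oy < oh; ++oy) {
            const int iy = oy * stride - pad + r;
            if (iy < 0 || iy >= H) continue;
            colq[base + oy] = xcol[iy];
          }
        }
      }
    }
  }
  return cols;
}

static arma::cube col2im(const arma::mat& cols, int H, int W, int C, int kh,
                         int kw, int stride, int pad, int oh, int ow) {
  arma::cube x(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    arma::mat& xc = x.slice(c);
    for (int s = 0; s < kw; ++s) {
      for (int r = 0; r < kh; ++r) {
        const int q = r + kh * s + kh * kw * c;
        const double* colq = cols.colptr(q);
        for (int ox = 0; ox < ow; ++ox) {
          const int ix = ox * stride - pad + s;
          if (ix < 0 || ix >= W) continue;
          double* xcol = xc.colptr(ix);
          const int base = oh * ox;
          for (int oy = 0; oy < oh; ++oy) {
            const int iy = oy * stride - pad + r;
            if (iy < 0 || iy >= H) continue;
            xcol[iy] += colq[base + oy];
          }
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export]]
arma::cube cpp_conv2d_fwd(const arma::cube& x, const arma::mat& w,
                          const arma::vec& b, int kh, int kw, int stride,
                          int pad) {
  const int H = x.n_rows, W = x.n_cols;
  const int oh = (H + 2 * pad - kh) / stride + 1;
  const int ow = (W + 2 * pad - kw) / stride + 1;
  const int cout = w.n_cols;
  arma::mat cols = im2col(x, kh, kw, stride, pad, oh, ow);
  arma::mat y = cols * w;
  y.each_row() += b.t();
  arma::cube out(oh, ow, cout);
  std::memcpy(out.memptr(), y.memptr(), sizeof(double) * y.n_elem);
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(const arma::cube& x, const arma::mat& w,
                    const arma::cube& gy, int kh, int kw, int stride,
                    int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int oh = gy.n_rows, ow = gy.n_cols, cout = gy.n_slices;
  arma::mat cols = im2col(x, kh, kw, stride, pad, oh, ow);
  arma::mat gym(oh * ow, cout);
  std::memcpy(gym.memptr(), gy.memptr(), sizeof(double) * gy.n_elem);
  arma::mat gw = cols.t() * gym;
  arma::vec gb = arma::sum(gym, 0).t();
  arma::mat gcols = gym * w.t();
  arma::cube gx = col2im(gcols, H, W, C, kh, kw, stride, pad, oh, ow);
  return List::create(Named("gx") = gx, Named("gw") = gw, Named("gb") = gb);
}
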