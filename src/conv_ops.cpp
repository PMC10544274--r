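// Core convolution primitives for the residual-correction network and the
// convolutional loss. Layout conventions (column-major, matching R arrays):
//   activations: cube (H, W, C)
//   weights:     4-d array with dim (kh, kw, C_in, C_out), flattened so that
//                row q = di + kh*(dj + kw*c) of the (kh*kw*C_in, C_out)
//                weight matrix corresponds to offset (di, dj) in channel c.
// Stencils are applied unflipped (cross-correlation); the loss-kernel bank is
// documented under the same convention so hand oracles stay unambiguous.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat im2col(const cube& xp, int kh, int kw, int stride, int Ho, int Wo) {
  const int Cin = xp.n_slices;
  mat col(Ho * (long long)Wo, kh * kw * Cin);
  for (int c = 0; c < Cin; ++c) {
    const mat& s = xp.slice(c);
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        int q = di + kh * (dj + kw * c);
        double* dst = col.colptr(q);
        for (int j = 0; j < Wo; ++j) {
          const double* src = s.colptr(dj + j * stride) + di;
          for (int i = 0; i < Ho; ++i) dst[i + (long long)j * Ho] = src[i * stride];
        }
      }
    }
  }
  return col;
}

static cube pad_cube(const cube& x, int pad) {
  if (pad == 0) return x;
  cube xp(x.n_rows + 2 * pad, x.n_cols + 2 * pad, x.n_slices, fill::zeros);
  xp.subcube(pad, pad, 0, pad + x.n_rows - 1, pad + x.n_cols - 1, x.n_slices - 1) = x;
  return xp;
}

// [[Rcpp::export]]
arma::cube cpp_conv2d_fwd(const arma::cube& x, const arma::mat& wmat,
                          const arma::vec& bias, int kh, int kw,
                          int stride, int pad) {
  const int Ho = (x.n_rows + 2 * pad - kh) / stride + 1;
  const int Wo = (x.n_cols + 2 * pad - kw) / stride + 1;
  const int Cout = wmat.n_cols;
  cube xp = pad_cube(x, pad);
  mat col = im2col(xp, kh, kw, stride, Ho, Wo);
  mat y = col * wmat;
  y.each_row() += bias.t();
  cube out(Ho, Wo, Cout);
  std::memcpy(out.memptr(), y.memptr(), sizeof(double) * y.n_elem);
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv2d_bwd(const arma::cube& x, const arma::mat& wmat,
                          const arma::cube& gy, int kh, int kw,
                          int stride, int pad) {
  const int Ho = gy.n_rows, Wo = gy.n_cols, Cout = gy.n_slices;
  const int Cin = x.n_slices;
  cube xp = pad_cube(x, pad);
  mat col = im2col(xp, kh, kw, stride, Ho, Wo);
  mat gym(const_cast<double*>(gy.memptr()), Ho * (long long)Wo, Cout, false, true);
  mat gw = col.t() * gym;
  vec gb = sum(gym, 0).t();
  mat gcol = gym * wmat.t();
  // scatter gcol back into padded-input gradient
  cube gxp(xp.n_rows, xp.n_cols, Cin, fill::zeros);
  for (int c = 0; c < Cin; ++c) {
    mat& s = gxp.slice(c);
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        int q = di + kh * (dj + kw * c);
        const double* src = gcol.colptr(q);
        for (int j = 0; j < Wo; ++j) {
          double* dst = s.colptr(dj + j * stride) + di;
          for (int i = 0; i < Ho; ++i) dst[i * stride] += src[i + (long long)j * Ho];
        }
      }
    }
  }
  cube gx = gxp.subcube(pad, pad, 0, pad + x.n_rows - 1, pad + x.n_cols - 1, Cin - 1);
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gw") = gw,
                            Rcpp::Named("gb") = gb);
}

// Valid-region 2-D cross-correlation of a single-channel image with a small
// stencil; used by the convolutional loss and the windowed quality metrics.
// [[Rcpp::export]]
arma::mat cpp_xcorr2_valid(const arma::mat& x, const arma::mat& k) {
  const int Ho = x.n_rows - k.n_rows + 1;
  const int Wo = x.n_cols - k.n_cols + 1;
  mat out(Ho, Wo, fill::zeros);
  for (unsigned dj = 0; dj < k.n_cols; ++dj)
    for (unsigned di = 0; di < k.n_rows; ++di) {
      double w = k(di, dj);
      if (w == 0.0) continue;
      out += w * x.submat(di, dj, di + Ho - 1, dj + Wo - 1);
    }
  return out;
}
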