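// Minimal 2-D conv/pool/upsample kernels for the contact-map refiner.
// Feature maps are arma::cube (rows = i, cols = j, slices = channels);
// 3x3 convolutions use zero padding and stride 1, realised as im2col + gemm
// so the heavy lifting happens inside BLAS.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// im2col for a 3x3 kernel: row (i + H*j), column (ki + 3*kj + 9*c) —
// matching the flattening order of an R array of dim c(3, 3, Cin, Cout).
static arma::mat im2col3(const arma::cube& x) {
  const arma::uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat out(H * W, 9 * C, arma::fill::zeros);
  for (arma::uword c = 0; c < C; ++c) {
    for (int kj = 0; kj < 3; ++kj) {
      for (int ki = 0; ki < 3; ++ki) {
        const arma::uword col = ki + 3 * kj + 9 * c;
        for (arma::uword j = 0; j < W; ++j) {
          const int sj = (int)j + kj - 1;
          if (sj < 0 || sj >= (int)W) continue;
          for (arma::uword i = 0; i < H; ++i) {
            const int si = (int)i + ki - 1;
            if (si < 0 || si >= (int)H) continue;
            out(i + H * j, col) = x(si, sj, c);
          }
        }
      }
    }
  }
  return out;
}

// scatter-add transpose of im2col3
static arma::cube col2im3(const arma::mat& cols, arma::uword H, arma::uword W,
                          arma::uword C) {
  arma::cube x(H, W, C, arma::fill::zeros);
  for (arma::uword c = 0; c < C; ++c) {
    for (int kj = 0; kj < 3; ++kj) {
      for (int ki = 0; ki < 3; ++ki) {
        const arma::uword col = ki + 3 * kj + 9 * c;
        for (arma::uword j = 0; j < W; ++j) {
          const int sj = (int)j + kj - 1;
          if (sj < 0 || sj >= (int)W) continue;
          for (arma::uword i = 0; i < H; ++i) {
            const int si = (int)i + ki - 1;
            if (si < 0 || si >= (int)H) continue;
            x(si, sj, c) += cols(i + H * j, col);
          }
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export]]
arma::cube cpp_conv3_fwd(const arma::cube& x, const arma::mat& w2,
                         const arma::vec& b) {
  const arma::uword H = x.n_rows, W = x.n_cols;
  const arma::uword Cout = w2.n_cols;
  arma::mat y = im2col3(x) * w2;          // (H*W) x Cout
  y.each_row() += b.t();
  arma::cube out(y.memptr(), H, W, Cout); // column-major matches (i, j) order
  return out;
}

// [[Rcpp::export]]
List cpp_conv3_bwd(const arma::cube& x, const arma::mat& w2,
                   const arma::cube& dy) {
  const arma::uword H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const arma::uword Cout = dy.n_slices;
  arma::mat dym(const_cast<double*>(dy.memptr()), H * W, Cout, false, true);
  arma::mat xc = im2col3(x);
  arma::mat dw2 = xc.t() * dym;           // (9*Cin) x Cout
  arma::vec db = arma::sum(dym, 0).t();
  arma::mat dxc = dym * w2.t();
  arma::cube dx = col2im3(dxc, H, W, Cin);
  return List::create(_["dx"] = dx, _["dw"] = dw2, _["db"] = db);
}

// 2x2 max pool, stride 2; H and W must be even. Returns pooled map plus the
// within-block argmax (0..3, code = a + 2*b for offset (a, b)).
// [[Rcpp::export]]
List cpp_maxpool2_fwd(const arma::cube& x) {
  const arma::uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const arma::uword Ho = H / 2, Wo = W / 2;
  arma::cube y(Ho, Wo, C);
  arma::ucube idx(Ho, Wo, C);
  for (arma::uword c = 0; c < C; ++c)
    for (arma::uword j = 0; j < Wo; ++j)
      for (arma::uword i = 0; i < Ho; ++i) {
        double best = x(2 * i, 2 * j, c);
        arma::uword code = 0;
        for (int b = 0; b < 2; ++b)
          for (int a = 0; a < 2; ++a) {
            const double v = x(2 * i + a, 2 * j + b, c);
            if (v > best) { best = v; code = a + 2 * b; }
          }
        y(i, j, c) = best;
        idx(i, j, c) = code;
      }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_bwd(const arma::ucube& idx, const arma::cube& dy) {
  const arma::uword Ho = dy.n_rows, Wo = dy.n_cols, C = dy.n_slices;
  arma::cube dx(2 * Ho, 2 * Wo, C, arma::fill::zeros);
  for (arma::uword c = 0; c < C; ++c)
    for (arma::uword j = 0; j < Wo; ++j)
      for (arma::uword i = 0; i < Ho; ++i) {
        const arma::uword code = idx(i, j, c);
        dx(2 * i + (code % 2), 2 * j + (code / 2), c) = dy(i, j, c);
      }
  return dx;
}

// nearest-neighbour 2x upsampling
// [[Rcpp::export]]
arma::cube cpp_upsample2_fwd(const arma::cube& x) {
  const arma::uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube y(2 * H, 2 * W, C);
  for (arma::uword c = 0; c < C; ++c)
    for (arma::uword j = 0; j < W; ++j)
      for (arma::uword i = 0; i < H; ++i) {
        const double v = x(i, j, c);
        y(2 * i, 2 * j, c) = v;
        y(2 * i + 1, 2 * j, c) = v;
        y(2 * i, 2 * j + 1, c) = v;
        y(2 * i + 1, 2 * j + 1, c) = v;
      }
  return y;
}

// [[Rcpp::export]]
arma::cube cpp_upsample2_bwd(const arma::cube& dy) {
  const arma::uword H = dy.n_rows / 2, W = dy.n_cols / 2, C = dy.n_slices;
  arma::cube dx(H, W, C);
  for (arma::uword c = 0; c < C; ++c)
    for (arma::uword j = 0; j < W; ++j)
      for (arma::uword i = 0; i < H; ++i)
        dx(i, j, c) = dy(2 * i, 2 * j, c) + dy(2 * i + 1, 2 * j, c) +
                      dy(2 * i, 2 * j + 1, c) + dy(2 * i + 1, 2 * j + 1, c);
  return dx;
}
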