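// Low-level kernels for the small encoder-decoder segmenter.
//
// Feature maps are arma::mat with one row per pixel and one column per
// channel; the pixel index is p = row + H * col, matching the column-major
// vectorisation of an R matrix. 3x3 convolutions use zero padding and are
// evaluated as im2col followed by a BLAS matrix multiply.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat im2col3(const mat& x, const int H, const int W) {
  const int C = x.n_cols;
  mat K(H * W, 9 * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        const int kcol = 9 * c + (dc + 1) * 3 + (dr + 1);
        for (int col = 0; col < W; ++col) {
          const int sc = col + dc;
          if (sc < 0 || sc >= W) continue;
          const int r0 = std::max(0, -dr);
          const int r1 = std::min(H, H - dr);
          for (int row = r0; row < r1; ++row) {
            K(row + H * col, kcol) = x(row + dr + H * sc, c);
          }
        }
      }
    }
  }
  return K;
}

static mat col2im3(const mat& gK, const int H, const int W, const int C) {
  mat gx(H * W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        const int kcol = 9 * c + (dc + 1) * 3 + (dr + 1);
        for (int col = 0; col < W; ++col) {
          const int sc = col + dc;
          if (sc < 0 || sc >= W) continue;
          const int r0 = std::max(0, -dr);
          const int r1 = std::min(H, H - dr);
          for (int row = r0; row < r1; ++row) {
            gx(row + dr + H * sc, c) += gK(row + H * col, kcol);
          }
        }
      }
    }
  }
  return gx;
}

// [[Rcpp::export]]
arma::mat cpp_conv3_fwd(const arma::mat& x, const int H, const int W,
                        const arma::mat& wmat, const arma::rowvec& b) {
  mat out = im2col3(x, H, W) * wmat;
  out.each_row() += b;
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv3_bwd(const arma::mat& x, const int H, const int W,
                         const arma::mat& wmat, const arma::mat& gout) {
  mat K = im2col3(x, H, W);
  mat gw = K.t() * gout;
  rowvec gb = sum(gout, 0);
  mat gx = col2im3(gout * wmat.t(), H, W, x.n_cols);
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gw") = gw,
                            Rcpp::Named("gb") = gb);
}

// [[Rcpp::export]]
arma::mat cpp_pool2_fwd(const arma::mat& x, const int H, const int W) {
  const int C = x.n_cols, Hs = H / 2, Ws = W / 2;
  mat out(Hs * Ws, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int col = 0; col < Ws; ++col) {
      for (int row = 0; row < Hs; ++row) {
        const int r = 2 * row, cc = 2 * col;
        out(row + Hs * col, c) = 0.25 * (x(r + H * cc, c) + x(r + 1 + H * cc, c) +
                                         x(r + H * (cc + 1), c) + x(r + 1 + H * (cc + 1), c));
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_pool2_bwd(const arma::mat& g, const int H, const int W) {
  const int C = g.n_cols, Hs = H / 2, Ws = W / 2;
  mat gx(H * W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int col = 0; col < Ws; ++col) {
      for (int row = 0; row < Hs; ++row) {
        const double v = 0.25 * g(row + Hs * col, c);
        const int r = 2 * row, cc = 2 * col;
        gx(r + H * cc, c) = v;
        gx(r + 1 + H * cc, c) = v;
        gx(r + H * (cc + 1), c) = v;
        gx(r + 1 + H * (cc + 1), c) = v;
      }
    }
  }
  return gx;
}

// Nearest-neighbour 2x upsampling from an Hs x Ws grid to 2Hs x 2Ws.
// [[Rcpp::export]]
arma::mat cpp_up2_fwd(const arma::mat& x, const int Hs, const int Ws) {
  const int C = x.n_cols, H = 2 * Hs;
  mat out(4 * Hs * Ws, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int col = 0; col < Ws; ++col) {
      for (int row = 0; row < Hs; ++row) {
        const double v = x(row + Hs * col, c);
        const int r = 2 * row, cc = 2 * col;
        out(r + H * cc, c) = v;
        out(r + 1 + H * cc, c) = v;
        out(r + H * (cc + 1), c) = v;
        out(r + 1 + H * (cc + 1), c) = v;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_up2_bwd(const arma::mat& g, const int Hs, const int Ws) {
  const int C = g.n_cols, H = 2 * Hs;
  mat gx(Hs * Ws, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int col = 0; col < Ws; ++col) {
      for (int row = 0; row < Hs; ++row) {
        const int r = 2 * row, cc = 2 * col;
        gx(row + Hs * col, c) = g(r + H * cc, c) + g(r + 1 + H * cc, c) +
          g(r + H * (cc + 1), c) + g(r + 1 + H * (cc + 1), c);
      }
    }
  }
  return gx;
}
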