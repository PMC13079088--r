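// Minimal conv-net primitives for the compact keypoint detector.
// Feature maps are arma::cube (H x W x C); weights are (Cout x k*k*Cin)
// matrices so both passes reduce to one GEMM over an im2col buffer.
// Row layout inside a column: r = ci*k*k + ky*k + kx (kx fastest).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline int out_dim(int n, int k, int stride, int pad, int dil) {
  int ke = (k - 1) * dil + 1;
  return (n + 2 * pad - ke) / stride + 1;
}

static void im2col(const cube& x, int k, int stride, int pad, int dil,
                   mat& col) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = out_dim(H, k, stride, pad, dil);
  const int Wo = out_dim(W, k, stride, pad, dil);
  col.set_size(C * k * k, Ho * Wo);
  col.zeros();
  for (int c = 0; c < C; ++c) {
    const mat& xs = x.slice(c);
    for (int ky = 0; ky < k; ++ky) {
      for (int kx = 0; kx < k; ++kx) {
        const int r = c * k * k + ky * k + kx;
        for (int j = 0; j < Wo; ++j) {
          const int wx = j * stride - pad + kx * dil;
          if (wx < 0 || wx >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            const int wy = i * stride - pad + ky * dil;
            if (wy < 0 || wy >= H) continue;
            col(r, i + j * Ho) = xs(wy, wx);
          }
        }
      }
    }
  }
}

static void col2im(const mat& col, int H, int W, int C, int k, int stride,
                   int pad, int dil, cube& x) {
  const int Ho = out_dim(H, k, stride, pad, dil);
  const int Wo = out_dim(W, k, stride, pad, dil);
  x.set_size(H, W, C);
  x.zeros();
  for (int c = 0; c < C; ++c) {
    mat& xs = x.slice(c);
    for (int ky = 0; ky < k; ++ky) {
      for (int kx = 0; kx < k; ++kx) {
        const int r = c * k * k + ky * k + kx;
        for (int j = 0; j < Wo; ++j) {
          const int wx = j * stride - pad + kx * dil;
          if (wx < 0 || wx >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            const int wy = i * stride - pad + ky * dil;
            if (wy < 0 || wy >= H) continue;
            xs(wy, wx) += col(r, i + j * Ho);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube conv2d_fwd(const arma::cube& x, const arma::mat& w,
                      const arma::vec& b, int k, int stride, int pad,
                      int dil) {
  const int H = x.n_rows, W = x.n_cols;
  const int Ho = out_dim(H, k, stride, pad, dil);
  const int Wo = out_dim(W, k, stride, pad, dil);
  const int Cout = w.n_rows;
  mat col;
  im2col(x, k, stride, pad, dil, col);
  mat out = w * col;              // Cout x (Ho*Wo)
  out.each_col() += b;
  cube y(Ho, Wo, Cout);
  for (int c = 0; c < Cout; ++c)
    y.slice(c) = reshape(out.row(c).t(), Ho, Wo);
  return y;
}

// [[Rcpp::export]]
Rcpp::List conv2d_bwd(const arma::cube& x, const arma::mat& w,
                      const arma::cube& gy, int k, int stride, int pad,
                      int dil) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Ho = gy.n_rows, Wo = gy.n_cols, Cout = gy.n_slices;
  mat g(Cout, Ho * Wo);
  for (int c = 0; c < Cout; ++c)
    g.row(c) = vectorise(gy.slice(c)).t();
  mat col;
  im2col(x, k, stride, pad, dil, col);
  mat gw = g * col.t();           // Cout x (Cin*k*k)
  vec gb = sum(g, 1);
  mat gcol = w.t() * g;           // (Cin*k*k) x (Ho*Wo)
  cube gx;
  col2im(gcol, H, W, Cin, k, stride, pad, dil, gx);
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gw") = gw,
                            Rcpp::Named("gb") = gb);
}

// [[Rcpp::export]]
arma::cube upsample_nn_fwd(const arma::cube& x, int f) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube y(H * f, W * f, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W * f; ++j)
      for (int i = 0; i < H * f; ++i)
        y(i, j, c) = x(i / f, j / f, c);
  return y;
}

// [[Rcpp::export]]
arma::cube upsample_nn_bwd(const arma::cube& gy, int f) {
  const int Ho = gy.n_rows / f, Wo = gy.n_cols / f, C = gy.n_slices;
  cube gx(Ho, Wo, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (unsigned int j = 0; j < gy.n_cols; ++j)
      for (unsigned int i = 0; i < gy.n_rows; ++i)
        gx(i / f, j / f, c) += gy(i, j, c);
  return gx;
}
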