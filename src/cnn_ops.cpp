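// Convolution / pooling primitives for the compact CNN.
// Layout: activations are H x W x C cubes; conv weights are
// (C_out) x (k*k*C_in) matrices acting on im2col patches ('same' zero
// padding, stride 1, odd k).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// Patch matrix: (k*k*C) x (H*W), pixel p = i + j*H (column-major).
static mat im2col_same(const cube& x, const int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices, r = k / 2;
  mat cols(k * k * C, H * W, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& xc = x.slice(c);
    for (int dj = -r; dj <= r; ++dj) {
      for (int di = -r; di <= r; ++di) {
        const int row = c * k * k + (dj + r) * k + (di + r);
        for (int j = 0; j < W; ++j) {
          const int js = j + dj;
          if (js < 0 || js >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int is = i + di;
            if (is < 0 || is >= H) continue;
            cols(row, i + j * H) = xc(is, js);
          }
        }
      }
    }
  }
  return cols;
}

// Adjoint of im2col_same: scatter-add patch gradients back to the image.
static cube col2im_same(const mat& cols, const int H, const int W,
                        const int C, const int k) {
  const int r = k / 2;
  cube x(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& xc = x.slice(c);
    for (int dj = -r; dj <= r; ++dj) {
      for (int di = -r; di <= r; ++di) {
        const int row = c * k * k + (dj + r) * k + (di + r);
        for (int j = 0; j < W; ++j) {
          const int js = j + dj;
          if (js < 0 || js >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int is = i + di;
            if (is < 0 || is >= H) continue;
            xc(is, js) += cols(row, i + j * H);
          }
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export]]
arma::cube cnn_conv2d_forward(const arma::cube& x, const arma::mat& w,
                              const arma::vec& b, const int k) {
  const int H = x.n_rows, W = x.n_cols, Cout = w.n_rows;
  mat y = w * im2col_same(x, k);
  y.each_col() += b;
  cube out(H, W, Cout);
  for (int c = 0; c < Cout; ++c)
    out.slice(c) = reshape(y.row(c).t(), H, W);
  return out;
}

// [[Rcpp::export]]
Rcpp::List cnn_conv2d_backward(const arma::cube& x, const arma::mat& w,
                               const arma::cube& dy, const int k) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices, Cout = dy.n_slices;
  mat dy_mat(Cout, H * W);
  for (int c = 0; c < Cout; ++c)
    dy_mat.row(c) = vectorise(dy.slice(c)).t();
  mat cols = im2col_same(x, k);
  mat dw = dy_mat * cols.t();
  vec db = sum(dy_mat, 1);
  cube dx = col2im_same(w.t() * dy_mat, H, W, Cin, k);
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}

// 2x2 max pooling, stride 2 (H, W even). Returns pooled cube and the
// 1-based linear index of each winner for the backward pass.
// [[Rcpp::export]]
Rcpp::List cnn_maxpool2_forward(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  cube y(Ho, Wo, C);
  ucube idx(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = -datum::inf;
        uword best_lin = 0;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            const int ii = 2 * i + di, jj = 2 * j + dj;
            const double v = x(ii, jj, c);
            if (v > best) {
              best = v;
              best_lin = (uword)c * H * W + (uword)jj * H + ii;
            }
          }
        }
        y(i, j, c) = best;
        idx(i, j, c) = best_lin + 1;  // 1-based for R
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube cnn_maxpool2_backward(const arma::ucube& idx, const arma::cube& dy,
                                 const int H, const int W) {
  const int C = dy.n_slices;
  cube dx(H, W, C, fill::zeros);
  const uword n = idx.n_elem;
  for (uword t = 0; t < n; ++t)
    dx(idx(t) - 1) += dy(t);
  return dx;
}

// Non-overlapping f x f average pooling (used as the fixed input stem).
// [[Rcpp::export]]
arma::mat cnn_avgpool(const arma::mat& x, const int f) {
  const int Ho = x.n_rows / f, Wo = x.n_cols / f;
  mat y(Ho, Wo, fill::zeros);
  for (int j = 0; j < Wo; ++j)
    for (int i = 0; i < Ho; ++i)
      y(i, j) = accu(x.submat(i * f, j * f, i * f + f - 1, j * f + f - 1));
  return y / (f * f);
}
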