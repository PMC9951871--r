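// Minimal 2D convolution kernels for the U-Net: stride-1 'same' convolution
// (square kernel, zero padding), 2x2 max pooling, and 2x2 stride-2
// transposed convolution, each with forward and backward passes.
//
// Layouts follow R's column-major arrays:
//   feature maps: H x W x C cubes
//   conv kernels: k x k x Cin x Cout arrays (index di, dj, ci, co)
// Convolutions are evaluated as a GEMM against an im2col matrix whose row
// index ci*k*k + dj*k + di matches the kernel's natural linear order, so
// the kernel array reshapes directly into the GEMM operand.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat im2col(const cube& x, int k, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat col(k * k * C, H * W, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int row = c * k * k + dj * k + di;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - pad;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + di - pad;
            if (si < 0 || si >= H) continue;
            col(row, j * H + i) = x(si, sj, c);
          }
        }
      }
    }
  }
  return col;
}

static void col2im_acc(const mat& dcol, cube& dx, int k, int pad) {
  const int H = dx.n_rows, W = dx.n_cols, C = dx.n_slices;
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int row = c * k * k + dj * k + di;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - pad;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + di - pad;
            if (si < 0 || si >= H) continue;
            dx(si, sj, c) += dcol(row, j * H + i);
          }
        }
      }
    }
  }
}

// weights arrive as a k*k*Cin x Cout matrix (reshaped in R); rows follow
// the im2col row order.

// [[Rcpp::export(name = ".conv2d_fwd_cpp")]]
arma::cube conv2d_fwd_cpp(const arma::cube& x, const arma::mat& wmat,
                          int k, int pad) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = wmat.n_cols;
  mat col = im2col(x, k, pad);
  mat y = wmat.t() * col;  // Cout x HW
  cube out(H, W, Cout);
  for (int co = 0; co < Cout; ++co)
    out.slice(co) = reshape(y.row(co), H, W);
  return out;
}

// [[Rcpp::export(name = ".conv2d_bwd_cpp")]]
Rcpp::List conv2d_bwd_cpp(const arma::cube& x, const arma::mat& wmat,
                          const arma::cube& dy, int k, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Cout = dy.n_slices;
  mat dymat(Cout, H * W);
  for (int co = 0; co < Cout; ++co)
    dymat.row(co) = reshape(dy.slice(co), 1, H * W);
  mat col = im2col(x, k, pad);
  mat dw = col * dymat.t();          // (k*k*Cin) x Cout
  mat dcol = wmat * dymat;           // (k*k*Cin) x HW
  cube dx(H, W, C, fill::zeros);
  col2im_acc(dcol, dx, k, pad);
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dw") = dw);
}

// [[Rcpp::export(name = ".maxpool2_fwd_cpp")]]
Rcpp::List maxpool2_fwd_cpp(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  if (H % 2 || W % 2) Rcpp::stop("max pooling requires even spatial dimensions");
  const int h = H / 2, w = W / 2;
  cube y(h, w, C);
  Rcpp::IntegerVector idx(h * w * C);  // 0-based linear index into x
  int p = 0;
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < h; ++i) {
        double best = x(2 * i, 2 * j, c);
        int bi = 2 * i, bj = 2 * j;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            double v = x(2 * i + di, 2 * j + dj, c);
            if (v > best) { best = v; bi = 2 * i + di; bj = 2 * j + dj; }
          }
        y(i, j, c) = best;
        idx[p++] = bi + H * bj + H * W * c;
      }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export(name = ".maxpool2_bwd_cpp")]]
arma::cube maxpool2_bwd_cpp(const arma::cube& dy, const Rcpp::IntegerVector& idx,
                            int H, int W) {
  const int C = dy.n_slices;
  cube dx(H, W, C, fill::zeros);
  const int n = idx.size();
  const double* g = dy.memptr();
  double* d = dx.memptr();
  for (int p = 0; p < n; ++p) d[idx[p]] += g[p];
  return dx;
}

// transposed conv 2x2, stride 2: each input pixel paints one 2x2 output block
// weights: 2 x 2 x Cin x Cout array passed as (4*Cin) x Cout matrix with row
// order di + 2*dj + 4*ci.

// [[Rcpp::export(name = ".upconv2_fwd_cpp")]]
arma::cube upconv2_fwd_cpp(const arma::cube& x, const arma::mat& wmat) {
  const int h = x.n_rows, w = x.n_cols, Cin = x.n_slices;
  const int Cout = wmat.n_cols;
  cube y(2 * h, 2 * w, Cout, fill::zeros);
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int dj = 0; dj < 2; ++dj)
        for (int di = 0; di < 2; ++di) {
          const double wv = wmat(di + 2 * dj + 4 * ci, co);
          if (wv == 0) continue;
          for (int j = 0; j < w; ++j)
            for (int i = 0; i < h; ++i)
              y(2 * i + di, 2 * j + dj, co) += wv * x(i, j, ci);
        }
  return y;
}

// [[Rcpp::export(name = ".upconv2_bwd_cpp")]]
Rcpp::List upconv2_bwd_cpp(const arma::cube& x, const arma::mat& wmat,
                           const arma::cube& dy) {
  const int h = x.n_rows, w = x.n_cols, Cin = x.n_slices;
  const int Cout = wmat.n_cols;
  cube dx(h, w, Cin, fill::zeros);
  mat dw(4 * Cin, Cout, fill::zeros);
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int dj = 0; dj < 2; ++dj)
        for (int di = 0; di < 2; ++di) {
          const double wv = wmat(di + 2 * dj + 4 * ci, co);
          double acc = 0.0;
          for (int j = 0; j < w; ++j)
            for (int i = 0; i < h; ++i) {
              const double g = dy(2 * i + di, 2 * j + dj, co);
              acc += g * x(i, j, ci);
              dx(i, j, ci) += g * wv;
            }
          dw(di + 2 * dj + 4 * ci, co) = acc;
        }
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dw") = dw);
}
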