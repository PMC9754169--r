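#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Activation tensors are stored as (N*H*W) x C matrices. Each image slab is
// the column-major vectorisation of an H x W slice, so row index
// r = n*H*W + x*H + y (0-based, y = row within slice, x = column). This
// matches R's native array layout, letting the R side move between slice
// matrices and activation rows with plain dim<- reshapes.

// Gather the 3x3 neighbourhood (zero-padded) of every pixel into a
// (N*H*W) x (9*Cin) matrix. Offset order: dc in {-1,0,1} outer, dr inner;
// block k holds all Cin channels shifted by (dr, dc).
static void im2col3x3(const mat& X, const int N, const int H, const int W,
                      mat& col) {
  const int Cin = X.n_cols;
  const int HW = H * W;
  col.zeros(X.n_rows, 9 * Cin);
  int k = 0;
  for (int dc = -1; dc <= 1; ++dc) {
    for (int dr = -1; dr <= 1; ++dr, ++k) {
      const int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
      const int c0 = std::max(0, -dc), c1 = std::min(W, W - dc);
      if (r1 <= r0 || c1 <= c0) continue;
      const int len = r1 - r0;
      for (int ch = 0; ch < Cin; ++ch) {
        const double* src_col = X.colptr(ch);
        double* dst_col = col.colptr(k * Cin + ch);
        for (int n = 0; n < N; ++n) {
          const int base = n * HW;
          for (int cc = c0; cc < c1; ++cc) {
            std::memcpy(dst_col + base + cc * H + r0,
                        src_col + base + (cc + dc) * H + (r0 + dr),
                        sizeof(double) * len);
          }
        }
      }
    }
  }
}

// Scatter-add the adjoint of im2col3x3: dX(src) += dcol(dst).
static void col2im3x3(const mat& dcol, const int N, const int H, const int W,
                      const int Cin, mat& dX) {
  const int HW = H * W;
  dX.zeros(N * HW, Cin);
  int k = 0;
  for (int dc = -1; dc <= 1; ++dc) {
    for (int dr = -1; dr <= 1; ++dr, ++k) {
      const int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
      const int c0 = std::max(0, -dc), c1 = std::min(W, W - dc);
      if (r1 <= r0 || c1 <= c0) continue;
      const int len = r1 - r0;
      for (int ch = 0; ch < Cin; ++ch) {
        const double* d_col = dcol.colptr(k * Cin + ch);
        double* x_col = dX.colptr(ch);
        for (int n = 0; n < N; ++n) {
          const int base = n * HW;
          for (int cc = c0; cc < c1; ++cc) {
            const double* s = d_col + base + cc * H + r0;
            double* t = x_col + base + (cc + dc) * H + (r0 + dr);
            for (int i = 0; i < len; ++i) t[i] += s[i];
          }
        }
      }
    }
  }
}

// 3x3 same-padding convolution. W_mat is (9*Cin) x Cout, bias length Cout.
// [[Rcpp::export]]
arma::mat conv3x3_forward(const arma::mat& X, const arma::mat& W_mat,
                          const arma::vec& bias, const int N, const int H,
                          const int W) {
  mat col;
  im2col3x3(X, N, H, W, col);
  mat Y = col * W_mat;
  Y.each_row() += bias.t();
  return Y;
}

// [[Rcpp::export]]
Rcpp::List conv3x3_backward(const arma::mat& X, const arma::mat& W_mat,
                            const arma::mat& dY, const int N, const int H,
                            const int W) {
  mat col;
  im2col3x3(X, N, H, W, col);
  mat dW = col.t() * dY;
  vec db = sum(dY, 0).t();
  mat dcol = dY * W_mat.t();
  mat dX;
  col2im3x3(dcol, N, H, W, X.n_cols, dX);
  return Rcpp::List::create(Rcpp::Named("dX") = dX, Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// 2x2 max pooling, stride 2. H and W must be even. Returns pooled
// activations plus the 1-based source row index of each maximum.
// [[Rcpp::export]]
Rcpp::List maxpool2x2_forward(const arma::mat& X, const int N, const int H,
                              const int W) {
  const int C = X.n_cols;
  const int Ho = H / 2, Wo = W / 2;
  const int HWo = Ho * Wo, HW = H * W;
  mat Y(N * HWo, C);
  umat amax(N * HWo, C);
  for (int ch = 0; ch < C; ++ch) {
    const double* xc = X.colptr(ch);
    double* yc = Y.colptr(ch);
    uword* ac = amax.colptr(ch);
    for (int n = 0; n < N; ++n) {
      for (int cc = 0; cc < Wo; ++cc) {
        for (int rr = 0; rr < Ho; ++rr) {
          const int out = n * HWo + cc * Ho + rr;
          int best = n * HW + (2 * cc) * H + 2 * rr;
          double bv = xc[best];
          const int cand[3] = {n * HW + (2 * cc) * H + 2 * rr + 1,
                               n * HW + (2 * cc + 1) * H + 2 * rr,
                               n * HW + (2 * cc + 1) * H + 2 * rr + 1};
          for (int j = 0; j < 3; ++j) {
            if (xc[cand[j]] > bv) { bv = xc[cand[j]]; best = cand[j]; }
          }
          yc[out] = bv;
          ac[out] = (uword)(best + 1);
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("Y") = Y, Rcpp::Named("argmax") = amax);
}

// [[Rcpp::export]]
arma::mat maxpool2x2_backward(const arma::mat& dY, const arma::umat& argmax,
                              const int n_rows_in) {
  const int C = dY.n_cols;
  mat dX(n_rows_in, C, fill::zeros);
  for (int ch = 0; ch < C; ++ch) {
    const double* dyc = dY.colptr(ch);
    const uword* ac = argmax.colptr(ch);
    double* dxc = dX.colptr(ch);
    const uword n = dY.n_rows;
    for (uword i = 0; i < n; ++i) dxc[ac[i] - 1] += dyc[i];
  }
  return dX;
}

// Column-wise fused scale/shift: M[, j] * s[j] + b[j].
// [[Rcpp::export]]
arma::mat colscale_add(const arma::mat& M, const arma::vec& s,
                       const arma::vec& b) {
  mat out = M;
  out.each_row() %= s.t();
  out.each_row() += b.t();
  return out;
}

// Batch-norm input gradient: (dxhat - m1[j] - xhat[, j] * m2[j]) * inv_sd[j].
// [[Rcpp::export]]
arma::mat bn_backward_input(const arma::mat& dxhat, const arma::mat& xhat,
                            const arma::vec& m1, const arma::vec& m2,
                            const arma::vec& inv_sd) {
  mat out = dxhat;
  out.each_row() -= m1.t();
  out -= xhat.each_row() % m2.t();
  out.each_row() %= inv_sd.t();
  return out;
}
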