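// Low-level CPU kernels for the segmentation network.
//
// Feature maps are stored as (H*W) x C matrices with column-major spatial
// flattening (linear index p = r + c*H, matching how R flattens a matrix),
// so a map converts to/from an R matrix without copying semantics.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// im2col for a 3x3 window with zero padding (stride 1, "same" output).
// Column block o*C..(o+1)*C-1 holds the input shifted by offset o, where
// offsets enumerate (dr, dc) with dr fastest: o = (dc+1)*3 + (dr+1).
static mat im2col3(const mat& X, const int H, const int W) {
  const int C = X.n_cols;
  mat out(H * W, 9 * C, fill::zeros);
  for (int dc = -1; dc <= 1; ++dc) {
    for (int dr = -1; dr <= 1; ++dr) {
      const int o = (dc + 1) * 3 + (dr + 1);
      const int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
      const int c0 = std::max(0, -dc), c1 = std::min(W, W - dc);
      for (int ch = 0; ch < C; ++ch) {
        for (int c = c0; c < c1; ++c) {
          const int src = (c + dc) * H + (r0 + dr);
          const int dst = c * H + r0;
          std::memcpy(out.colptr(o * C + ch) + dst,
                      X.colptr(ch) + src,
                      sizeof(double) * (r1 - r0));
        }
      }
    }
  }
  return out;
}

// Scatter-add inverse of im2col3.
static mat col2im3(const mat& G, const int H, const int W, const int C) {
  mat dX(H * W, C, fill::zeros);
  for (int dc = -1; dc <= 1; ++dc) {
    for (int dr = -1; dr <= 1; ++dr) {
      const int o = (dc + 1) * 3 + (dr + 1);
      const int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
      const int c0 = std::max(0, -dc), c1 = std::min(W, W - dc);
      for (int ch = 0; ch < C; ++ch) {
        for (int c = c0; c < c1; ++c) {
          const int src = (c + dc) * H + (r0 + dr);
          const int dst = c * H + r0;
          double* acc = dX.colptr(ch) + src;
          const double* g = G.colptr(o * C + ch) + dst;
          for (int r = 0; r < r1 - r0; ++r) acc[r] += g[r];
        }
      }
    }
  }
  return dX;
}

// Space-preserving 3x3 convolution. Wt is (9*C_in) x C_out, b length C_out.
// [[Rcpp::export]]
arma::mat conv3_forward(const arma::mat& X, const int H, const int W,
                        const arma::mat& Wt, const arma::vec& b) {
  mat Y = im2col3(X, H, W) * Wt;
  Y.each_row() += b.t();
  return Y;
}

// im2col matrix alone, so a training step can reuse it in the backward pass.
// [[Rcpp::export]]
arma::mat conv3_im2col(const arma::mat& X, const int H, const int W) {
  return im2col3(X, H, W);
}

// [[Rcpp::export]]
arma::mat conv3_col2im(const arma::mat& G, const int H, const int W,
                       const int C) {
  return col2im3(G, H, W, C);
}

// [[Rcpp::export]]
Rcpp::List conv3_backward(const arma::mat& X, const int H, const int W,
                          const arma::mat& Wt, const arma::mat& dY) {
  const mat G = im2col3(X, H, W);
  mat dW = G.t() * dY;
  vec db = sum(dY, 0).t();
  mat dX = col2im3(dY * Wt.t(), H, W, X.n_cols);
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// Row-wise softmax (numerically stabilized).
// [[Rcpp::export]]
arma::mat softmax_rows_cpp(const arma::mat& L) {
  mat Z = exp(L.each_col() - max(L, 1));
  Z.each_col() /= sum(Z, 1);
  return Z;
}

// GEMM with a per-output-channel bias: Y = A * W + b.
// [[Rcpp::export]]
arma::mat mm_bias(const arma::mat& A, const arma::mat& W, const arma::vec& b) {
  mat Y = A * W;
  Y.each_row() += b.t();
  return Y;
}

// Fused batch-norm (given per-channel mean and 1/sd) + ReLU.
// Returns the activation and the normalized pre-scale map for the backward
// pass.
// [[Rcpp::export]]
Rcpp::List bn_relu_forward(const arma::mat& a, const arma::vec& mu,
                           const arma::vec& invstd, const arma::vec& gamma,
                           const arma::vec& beta) {
  mat xhat = a.each_row() - mu.t();
  xhat.each_row() %= invstd.t();
  mat act = xhat.each_row() % gamma.t();
  act.each_row() += beta.t();
  act = clamp(act, 0.0, datum::inf);
  return Rcpp::List::create(Rcpp::Named("act") = act,
                            Rcpp::Named("xhat") = xhat);
}

// Fused ReLU + batch-norm backward. d is the gradient at the activation.
// [[Rcpp::export]]
Rcpp::List bn_relu_backward(const arma::mat& d, const arma::mat& act,
                            const arma::mat& xhat, const arma::vec& gamma,
                            const arma::vec& invstd) {
  const double n = (double) d.n_rows;
  mat d2 = d % (act > 0);
  vec dgamma = sum(d2 % xhat, 0).t();
  vec dbeta = sum(d2, 0).t();
  mat dxhat = d2.each_row() % gamma.t();
  rowvec s1 = sum(dxhat, 0) / n;
  rowvec s2 = sum(dxhat % xhat, 0) / n;
  mat dx = dxhat;
  dx.each_row() -= s1;
  dx -= xhat.each_row() % s2;
  dx.each_row() %= invstd.t();
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dgamma") = dgamma,
                            Rcpp::Named("dbeta") = dbeta);
}

// 1x1 convolution is a plain matrix product; kept here for symmetry.
// [[Rcpp::export]]
arma::mat conv1_forward(const arma::mat& X, const arma::mat& Wt,
                        const arma::vec& b) {
  mat Y = X * Wt;
  Y.each_row() += b.t();
  return Y;
}

// 2x2 max pooling, stride 2. H and W must be even. Returns pooled map and
// the 1-based linear row index of each argmax for the backward pass.
// [[Rcpp::export]]
Rcpp::List maxpool2_forward(const arma::mat& X, const int H, const int W) {
  const int C = X.n_cols, Ho = H / 2, Wo = W / 2;
  mat Y(Ho * Wo, C);
  imat idx(Ho * Wo, C);
  for (int ch = 0; ch < C; ++ch) {
    const double* x = X.colptr(ch);
    for (int c = 0; c < Wo; ++c) {
      for (int r = 0; r < Ho; ++r) {
        const int p00 = (2 * c) * H + 2 * r;
        int best = p00;
        double v = x[p00];
        const int cand[3] = {p00 + 1, p00 + H, p00 + H + 1};
        for (int k = 0; k < 3; ++k)
          if (x[cand[k]] > v) { v = x[cand[k]]; best = cand[k]; }
        Y(c * Ho + r, ch) = v;
        idx(c * Ho + r, ch) = best + 1;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = Y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::mat maxpool2_backward(const arma::imat& idx, const arma::mat& dY,
                            const int n_in) {
  const int C = dY.n_cols;
  mat dX(n_in, C, fill::zeros);
  for (int ch = 0; ch < C; ++ch) {
    double* acc = dX.colptr(ch);
    const double* g = dY.colptr(ch);
    const sword* ix = idx.colptr(ch);
    for (uword i = 0; i < dY.n_rows; ++i) acc[ix[i] - 1] += g[i];
  }
  return dX;
}

// Nearest-neighbour 2x upsampling of an h x w map to 2h x 2w.
// [[Rcpp::export]]
arma::mat upsample2_forward(const arma::mat& X, const int h, const int w) {
  const int C = X.n_cols, H = 2 * h;
  mat Y(4 * h * w, C);
  for (int ch = 0; ch < C; ++ch) {
    const double* x = X.colptr(ch);
    double* y = Y.colptr(ch);
    for (int c = 0; c < w; ++c) {
      for (int r = 0; r < h; ++r) {
        const double v = x[c * h + r];
        const int p = (2 * c) * H + 2 * r;
        y[p] = v; y[p + 1] = v; y[p + H] = v; y[p + H + 1] = v;
      }
    }
  }
  return Y;
}

// Gradient of nearest 2x upsampling: sum each 2x2 output block.
// [[Rcpp::export]]
arma::mat upsample2_backward(const arma::mat& dY, const int H, const int W) {
  const int C = dY.n_cols, h = H / 2, w = W / 2;
  mat dX(h * w, C);
  for (int ch = 0; ch < C; ++ch) {
    const double* g = dY.colptr(ch);
    double* acc = dX.colptr(ch);
    for (int c = 0; c < w; ++c) {
      for (int r = 0; r < h; ++r) {
        const int p = (2 * c) * H + 2 * r;
        acc[c * h + r] = g[p] + g[p + 1] + g[p + H] + g[p + H + 1];
      }
    }
  }
  return dX;
}
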