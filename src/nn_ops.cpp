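// Convolutional building blocks used by the detector, the registration
// network and the classifiers. Feature maps are arma::cube with dimensions
// (H, W, C); weights are (out_c) x (in_c*k*k) matrices with column index
// c*k*k + kr*k + kc (channel-major, then kernel row, then kernel column).
// Forward passes do not cache; backward recomputes im2col, trading a little
// CPU for memory.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2col(const arma::cube& x, int k, int stride, int pad,
                        int& ho, int& wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  ho = (H + 2 * pad - k) / stride + 1;
  wo = (W + 2 * pad - k) / stride + 1;
  arma::mat cols(C * k * k, ho * wo, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kr = 0; kr < k; ++kr) {
      for (int kc = 0; kc < k; ++kc) {
        const int row = c * k * k + kr * k + kc;
        for (int i = 0; i < ho; ++i) {
          const int r = i * stride + kr - pad;
          if (r < 0 || r >= H) continue;
          for (int j = 0; j < wo; ++j) {
            const int cc = j * stride + kc - pad;
            if (cc < 0 || cc >= W) continue;
            cols(row, i + j * ho) = x(r, cc, c);
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
arma::cube cpp_conv_fwd(const arma::cube& x, const arma::mat& W,
                        const arma::vec& b, int k, int stride, int pad) {
  int ho, wo;
  arma::mat cols = im2col(x, k, stride, pad, ho, wo);
  arma::mat y = W * cols;        // (out_c) x (ho*wo)
  y.each_col() += b;
  const int out_c = W.n_rows;
  arma::cube out(ho, wo, out_c);
  for (int c = 0; c < out_c; ++c) {
    arma::mat m(ho, wo);
    for (int j = 0; j < wo; ++j)
      for (int i = 0; i < ho; ++i) m(i, j) = y(c, i + j * ho);
    out.slice(c) = m;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv_bwd(const arma::cube& x, const arma::mat& W, const arma::cube& dy,
                  int k, int stride, int pad) {
  const int H = x.n_rows, Wd = x.n_cols, C = x.n_slices;
  int ho, wo;
  arma::mat cols = im2col(x, k, stride, pad, ho, wo);
  const int out_c = dy.n_slices;
  arma::mat dy_mat(out_c, ho * wo);
  for (int c = 0; c < out_c; ++c)
    for (int j = 0; j < wo; ++j)
      for (int i = 0; i < ho; ++i) dy_mat(c, i + j * ho) = dy(i, j, c);
  arma::mat dW = dy_mat * cols.t();
  arma::vec db = arma::sum(dy_mat, 1);
  arma::mat dcols = W.t() * dy_mat;  // (C*k*k) x (ho*wo)
  arma::cube dx(H, Wd, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kr = 0; kr < k; ++kr) {
      for (int kc = 0; kc < k; ++kc) {
        const int row = c * k * k + kr * k + kc;
        for (int i = 0; i < ho; ++i) {
          const int r = i * stride + kr - pad;
          if (r < 0 || r >= H) continue;
          for (int j = 0; j < wo; ++j) {
            const int cc = j * stride + kc - pad;
            if (cc < 0 || cc >= Wd) continue;
            dx(r, cc, c) += dcols(row, i + j * ho);
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// 2x2 max pooling, stride 2. Returns pooled cube and argmax codes 0..3
// (2*dr + dc within each pooling window).
// [[Rcpp::export]]
List cpp_maxpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int ho = H / 2, wo = W / 2;
  arma::cube y(ho, wo, C);
  arma::ucube arg(ho, wo, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < wo; ++j)
      for (int i = 0; i < ho; ++i) {
        double best = x(2 * i, 2 * j, c);
        unsigned code = 0;
        for (int dr = 0; dr < 2; ++dr)
          for (int dc = 0; dc < 2; ++dc) {
            double v = x(2 * i + dr, 2 * j + dc, c);
            if (v > best) { best = v; code = 2 * dr + dc; }
          }
        y(i, j, c) = best;
        arg(i, j, c) = code;
      }
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_bwd(const arma::cube& dy, const arma::ucube& arg,
                            int H, int W) {
  const int ho = dy.n_rows, wo = dy.n_cols, C = dy.n_slices;
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < wo; ++j)
      for (int i = 0; i < ho; ++i) {
        unsigned code = arg(i, j, c);
        dx(2 * i + code / 2, 2 * j + code % 2, c) += dy(i, j, c);
      }
  return dx;
}

// [[Rcpp::export]]
arma::cube cpp_avgpool2_fwd(const arma::cube& x) {
  const int ho = x.n_rows / 2, wo = x.n_cols / 2, C = x.n_slices;
  arma::cube y(ho, wo, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < wo; ++j)
      for (int i = 0; i < ho; ++i)
        y(i, j, c) = 0.25 * (x(2 * i, 2 * j, c) + x(2 * i + 1, 2 * j, c) +
                             x(2 * i, 2 * j + 1, c) + x(2 * i + 1, 2 * j + 1, c));
  return y;
}

// [[Rcpp::export]]
arma::cube cpp_avgpool2_bwd(const arma::cube& dy, int H, int W) {
  const int ho = dy.n_rows, wo = dy.n_cols, C = dy.n_slices;
  arma::cube dx(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < wo; ++j)
      for (int i = 0; i < ho; ++i) {
        double g = 0.25 * dy(i, j, c);
        dx(2 * i, 2 * j, c) = g;
        dx(2 * i + 1, 2 * j, c) = g;
        dx(2 * i, 2 * j + 1, c) = g;
        dx(2 * i + 1, 2 * j + 1, c) = g;
      }
  return dx;
}

// Nearest-neighbour 2x upsampling and its adjoint.
// [[Rcpp::export]]
arma::cube cpp_upsample2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        double v = x(i, j, c);
        y(2 * i, 2 * j, c) = v;
        y(2 * i + 1, 2 * j, c) = v;
        y(2 * i, 2 * j + 1, c) = v;
        y(2 * i + 1, 2 * j + 1, c) = v;
      }
  return y;
}

// [[Rcpp::export]]
arma::cube cpp_upsample2_bwd(const arma::cube& dy) {
  const int H = dy.n_rows / 2, W = dy.n_cols / 2, C = dy.n_slices;
  arma::cube dx(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        dx(i, j, c) = dy(2 * i, 2 * j, c) + dy(2 * i + 1, 2 * j, c) +
                      dy(2 * i, 2 * j + 1, c) + dy(2 * i + 1, 2 * j + 1, c);
  return dx;
}
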