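// Compiled kernels for the segmentation network: stride-1 dilated 2-D
// convolution (im2col + GEMM), depthwise convolution, 2x2 max pooling,
// nearest-neighbour 2x upsampling, and weighted softmax cross-entropy.
// All tensors are H x W x C arma::cube (column-major, matching R arrays).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;

// "same" padding for odd k: pad = dil*(k-1)/2
static mat im2col(const cube& x, const int k, const int dil) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int pad = dil * (k - 1) / 2;
  mat cols(k * k * C, (size_t)H * W, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        const int row = c * k * k + kj * k + ki;
        const int di = ki * dil - pad, dj = kj * dil - pad;
        const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
        const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        for (int j = j0; j < j1; ++j) {
          const double* src = x.slice_colptr(c, j + dj);
          double* dst = cols.colptr((size_t)j * H);
          for (int i = i0; i < i1; ++i)
            dst[(size_t)i * cols.n_rows + row] = src[i + di];
        }
      }
  return cols;
}

static cube col2im(const mat& cols, const int H, const int W, const int C,
                   const int k, const int dil) {
  const int pad = dil * (k - 1) / 2;
  cube x(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        const int row = c * k * k + kj * k + ki;
        const int di = ki * dil - pad, dj = kj * dil - pad;
        const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
        const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        for (int j = j0; j < j1; ++j) {
          double* dst = x.slice_colptr(c, j + dj);
          const double* src = cols.colptr((size_t)j * H);
          for (int i = i0; i < i1; ++i)
            dst[i + di] += src[(size_t)i * cols.n_rows + row];
        }
      }
  return x;
}

// w: (k*k*Cin) x Cout, b: Cout
// [[Rcpp::export]]
arma::cube conv2d_fwd(const arma::cube& x, const arma::mat& w,
                      const arma::vec& b, const int k, const int dil) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = w.n_cols;
  mat cols = im2col(x, k, dil);
  mat y = w.t() * cols;            // Cout x (H*W)
  y.each_col() += b;
  cube out(H, W, Cout);
  for (int o = 0; o < Cout; ++o)
    out.slice(o) = reshape(y.row(o), H, W);
  return out;
}

// [[Rcpp::export]]
List conv2d_bwd(const arma::cube& x, const arma::mat& w, const arma::cube& gy,
                const int k, const int dil) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Cout = gy.n_slices;
  mat gyf(Cout, (size_t)H * W);
  for (int o = 0; o < Cout; ++o)
    gyf.row(o) = vectorise(gy.slice(o)).t();
  mat cols = im2col(x, k, dil);
  mat gw = cols * gyf.t();
  vec gb = sum(gyf, 1);
  mat gcols = w * gyf;
  cube gx = col2im(gcols, H, W, C, k, dil);
  return List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gw") = gw,
                      Rcpp::Named("gb") = gb);
}

// depthwise: w is (k*k) x C, one spatial filter per channel
// [[Rcpp::export]]
arma::cube dwconv2d_fwd(const arma::cube& x, const arma::mat& w,
                        const arma::vec& b, const int k, const int dil) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int pad = dil * (k - 1) / 2;
  cube y(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        const double wv = w(kj * k + ki, c);
        const int di = ki * dil - pad, dj = kj * dil - pad;
        const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
        const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        for (int j = j0; j < j1; ++j) {
          const double* src = x.slice_colptr(c, j + dj);
          double* dst = y.slice_colptr(c, j);
          for (int i = i0; i < i1; ++i)
            dst[i] += wv * src[i + di];
        }
      }
    y.slice(c) += b(c);
  }
  return y;
}

// [[Rcpp::export]]
List dwconv2d_bwd(const arma::cube& x, const arma::mat& w, const arma::cube& gy,
                  const int k, const int dil) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int pad = dil * (k - 1) / 2;
  cube gx(H, W, C, fill::zeros);
  mat gw(k * k, C, fill::zeros);
  vec gb(C);
  for (int c = 0; c < C; ++c) {
    gb(c) = accu(gy.slice(c));
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        const double wv = w(kj * k + ki, c);
        double acc = 0.0;
        const int di = ki * dil - pad, dj = kj * dil - pad;
        const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
        const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        for (int j = j0; j < j1; ++j) {
          const double* g = gy.slice_colptr(c, j);
          const double* src = x.slice_colptr(c, j + dj);
          double* gsrc = gx.slice_colptr(c, j + dj);
          for (int i = i0; i < i1; ++i) {
            acc += g[i] * src[i + di];
            gsrc[i + di] += g[i] * wv;
          }
        }
        gw(kj * k + ki, c) = acc;
      }
  }
  return List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gw") = gw,
                      Rcpp::Named("gb") = gb);
}

// 2x2 max pooling, H and W even; idx stores the winning linear offset
// [[Rcpp::export]]
List maxpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  cube y(Ho, Wo, C);
  cube idx(Ho, Wo, C); // linear index into the input slice
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        double best = -datum::inf; int bi = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const int ii = 2 * i + di, jj = 2 * j + dj;
            const double v = x(ii, jj, c);
            if (v > best) { best = v; bi = ii + jj * H; }
          }
        y(i, j, c) = best;
        idx(i, j, c) = bi;
      }
  return List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube maxpool2_bwd(const arma::cube& gy, const arma::cube& idx,
                        const int H, const int W) {
  const int C = gy.n_slices, Ho = gy.n_rows, Wo = gy.n_cols;
  cube gx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* gs = gx.slice_memptr(c);
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i)
        gs[(size_t)idx(i, j, c)] += gy(i, j, c);
  }
  return gx;
}

// [[Rcpp::export]]
arma::cube upsample2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < 2 * W; ++j)
      for (int i = 0; i < 2 * H; ++i)
        y(i, j, c) = x(i / 2, j / 2, c);
  return y;
}

// [[Rcpp::export]]
arma::cube upsample2_bwd(const arma::cube& gy) {
  const int H = gy.n_rows / 2, W = gy.n_cols / 2, C = gy.n_slices;
  cube gx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < 2 * W; ++j)
      for (int i = 0; i < 2 * H; ++i)
        gx(i / 2, j / 2, c) += gy(i, j, c);
  return gx;
}

// Weighted softmax cross-entropy over pixels.
// scores: H x W x K, y: H x W integer matrix in 0..K-1, w: K class weights.
// loss = mean_px w[y] * (-log softmax(scores)[y]); grad wrt scores returned.
// [[Rcpp::export]]
List wce_loss(const arma::cube& scores, const arma::imat& y,
              const arma::vec& w) {
  const int H = scores.n_rows, W = scores.n_cols, K = scores.n_slices;
  const double N = (double)H * W;
  double loss = 0.0;
  cube g(H, W, K);
  vec s(K), p(K);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      for (int c = 0; c < K; ++c) s(c) = scores(i, j, c);
      const double m = s.max();
      p = exp(s - m);
      const double Z = accu(p);
      p /= Z;
      const int yi = y(i, j);
      const double wy = w(yi);
      loss += wy * (m + std::log(Z) - s(yi));
      for (int c = 0; c < K; ++c)
        g(i, j, c) = wy * (p(c) - (c == yi ? 1.0 : 0.0)) / N;
    }
  return List::create(Rcpp::Named("loss") = loss / N,
                      Rcpp::Named("g") = g);
}
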