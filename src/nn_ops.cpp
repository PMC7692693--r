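// Hot kernels for the 1D-CNN path: shifted-block convolution (no
// im2col materialization), fused batch-norm affine passes, ReLU and
// block max pooling. Maps are (batch * positions) x channels matrices,
// each example a contiguous block of `p` rows.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// im2col for a 'same'-padded batched 1D convolution: xc column block o
// holds x shifted by (o - half) within each example; out-of-range rows
// stay zero. One tight memcpy per (offset, example, channel).
static mat im2col1d(const mat& x, int n, int p, int k) {
  const int c_in = x.n_cols;
  const int half = (k - 1) / 2;
  mat xc(x.n_rows, k * c_in, fill::zeros);
  for (int o = 0; o < k; ++o) {
    const int d = o - half;
    const int t0 = std::max(0, -d);
    const int t1 = std::min(p - 1, p - 1 - d);
    if (t1 < t0) continue;
    const int len = t1 - t0 + 1;
    for (int c = 0; c < c_in; ++c) {
      const double* src = x.colptr(c);
      double* dst = xc.colptr(o * c_in + c);
      for (int s = 0; s < n; ++s) {
        std::memcpy(dst + s * p + t0, src + s * p + t0 + d,
                    len * sizeof(double));
      }
    }
  }
  return xc;
}

// 'same'-padded 1D convolution: one GEMM over the im2col buffer.
// W is (k*c_in) x c_out with offset o occupying rows [o*c_in, (o+1)*c_in)
// [[Rcpp::export]]
arma::mat cpp_conv1d_fwd(const arma::mat& x, int n, int p,
                         const arma::mat& W, const arma::vec& b, int k) {
  mat y = im2col1d(x, n, p, k) * W;
  y.each_row() += b.t();
  return y;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv1d_bwd(const arma::mat& x, const arma::mat& g,
                          const arma::mat& W, int n, int p, int k) {
  const int c_in = x.n_cols;
  const int half = (k - 1) / 2;
  mat xc = im2col1d(x, n, p, k);
  mat dW = xc.t() * g;
  mat dxc = g * W.t();
  // col2im: scatter-add the shifted column blocks back
  mat dx(x.n_rows, c_in, fill::zeros);
  for (int o = 0; o < k; ++o) {
    const int d = o - half;
    const int t0 = std::max(0, -d);
    const int t1 = std::min(p - 1, p - 1 - d);
    if (t1 < t0) continue;
    const int len = t1 - t0 + 1;
    for (int c = 0; c < c_in; ++c) {
      const double* src = dxc.colptr(o * c_in + c);
      double* dst = dx.colptr(c);
      for (int s = 0; s < n; ++s) {
        const double* sp = src + s * p + t0;
        double* dp = dst + s * p + t0 + d;
        for (int t = 0; t < len; ++t) dp[t] += sp[t];
      }
    }
  }
  rowvec db = sum(g, 0);
  return Rcpp::List::create(Rcpp::Named("W") = dW,
                            Rcpp::Named("b") = db.t(),
                            Rcpp::Named("dx") = dx);
}

// per-column mean and (population) variance in one pass
// [[Rcpp::export]]
Rcpp::List cpp_col_stats(const arma::mat& x) {
  rowvec mu = mean(x, 0);
  rowvec v = mean(square(x), 0) - square(mu);
  return Rcpp::List::create(Rcpp::Named("mean") = mu.t(),
                            Rcpp::Named("var") = v.t());
}

// y[, j] = x[, j] * a[j] + c[j], fused
// [[Rcpp::export]]
arma::mat cpp_affine_cols(const arma::mat& x, const arma::vec& a,
                          const arma::vec& c) {
  mat y = x;
  y.each_row() %= a.t();
  y.each_row() += c.t();
  return y;
}

// batch-norm input gradient: g*a1[j] - xhat*a2[j] - a3[j], fused
// [[Rcpp::export]]
arma::mat cpp_bn_bwd(const arma::mat& g, const arma::mat& xhat,
                     const arma::vec& a1, const arma::vec& a2,
                     const arma::vec& a3) {
  mat y = g;
  y.each_row() %= a1.t();
  mat t = xhat;
  t.each_row() %= a2.t();
  y -= t;
  y.each_row() -= a3.t();
  return y;
}

// [[Rcpp::export]]
arma::mat cpp_relu(const arma::mat& x) {
  return clamp(x, 0.0, datum::inf);
}

// gradient through ReLU given the forward OUTPUT y (y > 0 <=> pass)
// [[Rcpp::export]]
arma::mat cpp_relu_bwd(const arma::mat& g, const arma::mat& y) {
  mat d = g;
  d.elem(find(y <= 0)).zeros();
  return d;
}

// block max over s consecutive rows; sel returns 1-based flat indices
// (column-major) of the winners for the backward scatter
// [[Rcpp::export]]
Rcpp::List cpp_pool1d_fwd(const arma::mat& x, int s) {
  const int m = x.n_rows / s;
  const int c = x.n_cols;
  mat y(m, c);
  Rcpp::IntegerVector sel(m * c);
  for (int j = 0; j < c; ++j) {
    const double* col = x.colptr(j);
    for (int i = 0; i < m; ++i) {
      int w = 0;
      double best = col[i * s];
      for (int u = 1; u < s; ++u) {
        if (col[i * s + u] > best) { best = col[i * s + u]; w = u; }
      }
      y(i, j) = best;
      sel[j * m + i] = j * (int)x.n_rows + i * s + w + 1;
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y,
                            Rcpp::Named("sel") = sel);
}

// [[Rcpp::export]]
arma::mat cpp_pool1d_bwd(const arma::mat& g, const Rcpp::IntegerVector& sel,
                         int l_in) {
  mat dx(l_in, g.n_cols, fill::zeros);
  double* out = dx.memptr();
  const double* gi = g.memptr();
  for (int i = 0; i < (int)sel.size(); ++i) out[sel[i] - 1] = gi[i];
  return dx;
}
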