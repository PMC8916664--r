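// Batched 1D convolution kernels for the multimodal gait encoder-decoder.
//
// Activations are (B*T, C) matrices with row index b + B*(t-1), i.e. the
// column-major flattening of a (B, T, C) array, so time-block row ranges
// are contiguous. `it` is the T_out x k matrix of (1-based) input time
// stamps feeding each output time through each kernel tap; entries outside
// 1..T_in denote zero padding. Weights are (k*C_in) x C_out, tap-major.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export]]
arma::mat conv1d_fwd_cpp(const arma::mat& X2, const arma::mat& W,
                         const arma::vec& b, const arma::imat& it, int B) {
  const int T_out = it.n_rows, k = it.n_cols, C = X2.n_cols;
  const int T_in = X2.n_rows / B;
  mat Z(B * (size_t)T_out, W.n_cols, fill::zeros);
  mat G;
  for (int j = 0; j < k; ++j) {
    int t0 = -1, t1 = -1;
    for (int t = 0; t < T_out; ++t) {
      int i = it(t, j);
      if (i >= 1 && i <= T_in) { if (t0 < 0) t0 = t; t1 = t; }
    }
    if (t0 < 0) continue;
    const int n = t1 - t0 + 1;
    G.set_size(B * (size_t)n, C);
    for (int t = t0; t <= t1; ++t) {
      const int src = it(t, j) - 1;
      G.rows((t - t0) * B, (t - t0 + 1) * B - 1) =
        X2.rows(src * B, (src + 1) * B - 1);
    }
    Z.rows(t0 * B, (t1 + 1) * B - 1) += G * W.rows(j * C, (j + 1) * C - 1);
  }
  Z.each_row() += b.t();
  return Z;
}

// gradient w.r.t. the layer input
// [[Rcpp::export]]
arma::mat conv1d_bwd_input_cpp(const arma::mat& dZ, const arma::mat& W,
                               const arma::imat& it, int B, int T_in,
                               int C_in) {
  const int T_out = it.n_rows, k = it.n_cols;
  mat dX(B * (size_t)T_in, C_in, fill::zeros);
  mat P;
  for (int j = 0; j < k; ++j) {
    int t0 = -1, t1 = -1;
    for (int t = 0; t < T_out; ++t) {
      int i = it(t, j);
      if (i >= 1 && i <= T_in) { if (t0 < 0) t0 = t; t1 = t; }
    }
    if (t0 < 0) continue;
    P = dZ.rows(t0 * B, (t1 + 1) * B - 1) *
        W.rows(j * C_in, (j + 1) * C_in - 1).t();
    for (int t = t0; t <= t1; ++t) {
      const int src = it(t, j) - 1;
      dX.rows(src * B, (src + 1) * B - 1) +=
        P.rows((t - t0) * B, (t - t0 + 1) * B - 1);
    }
  }
  return dX;
}

// gradient w.r.t. the weights (the bias gradient is a colSums in R)
// [[Rcpp::export]]
arma::mat conv1d_bwd_dw_cpp(const arma::mat& dZ, const arma::mat& X2,
                            const arma::imat& it, int B) {
  const int T_out = it.n_rows, k = it.n_cols, C = X2.n_cols;
  const int T_in = X2.n_rows / B;
  mat dW(k * (size_t)C, dZ.n_cols, fill::zeros);
  mat G;
  for (int j = 0; j < k; ++j) {
    int t0 = -1, t1 = -1;
    for (int t = 0; t < T_out; ++t) {
      int i = it(t, j);
      if (i >= 1 && i <= T_in) { if (t0 < 0) t0 = t; t1 = t; }
    }
    if (t0 < 0) continue;
    const int n = t1 - t0 + 1;
    G.set_size(B * (size_t)n, C);
    for (int t = t0; t <= t1; ++t) {
      const int src = it(t, j) - 1;
      G.rows((t - t0) * B, (t - t0 + 1) * B - 1) =
        X2.rows(src * B, (src + 1) * B - 1);
    }
    dW.rows(j * C, (j + 1) * C - 1) =
      G.t() * dZ.rows(t0 * B, (t1 + 1) * B - 1);
  }
  return dW;
}

// [[Rcpp::export]]
arma::mat relu_cpp(arma::mat X) {
  X.for_each([](double& v) { if (v < 0) v = 0; });
  return X;
}

// [[Rcpp::export]]
arma::mat relu_bwd_cpp(arma::mat dY, const arma::mat& Z) {
  const size_t n = dY.n_elem;
  double* d = dY.memptr();
  const double* z = Z.memptr();
  for (size_t i = 0; i < n; ++i) if (z[i] <= 0) d[i] = 0;
  return dY;
}

// in-place Adam update; p, m, v are uniquely owned by the training loop
// [[Rcpp::export]]
void adam_update_cpp(Rcpp::NumericVector p, Rcpp::NumericVector m,
                     Rcpp::NumericVector v, Rcpp::NumericVector g,
                     double lr, double b1, double b2, double c1, double c2,
                     double eps) {
  const R_xlen_t n = p.size();
  double *pp = p.begin(), *pm = m.begin(), *pv = v.begin(), *pg = g.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    pm[i] = b1 * pm[i] + (1 - b1) * pg[i];
    pv[i] = b2 * pv[i] + (1 - b2) * pg[i] * pg[i];
    pp[i] -= lr * (pm[i] / c1) / (std::sqrt(pv[i] / c2) + eps);
  }
}
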