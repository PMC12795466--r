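// Whole-transformer-block kernels: graph-sparsified multi-head attention,
// residual + batch norm, feed-forward. Semantics match the R reference path
// (unit tests compare both against dense neighbor-loop oracles and finite
// differences).
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;
using Rcpp::List;
using Rcpp::Named;

static void masked_softmax(mat& S, const mat& ghat) {
  const int n = S.n_rows;
  vec m(n, fill::zeros), s(n, fill::zeros);
  const double* g = ghat.memptr();
  double* sp = S.memptr();
  for (int j = 0; j < n; ++j) {
    const double* gc = g + (size_t)j * n;
    const double* sc = sp + (size_t)j * n;
    for (int i = 0; i < n; ++i)
      if (gc[i] > 0 && sc[i] > m(i)) m(i) = sc[i];
  }
  for (int j = 0; j < n; ++j) {
    const double* gc = g + (size_t)j * n;
    double* sc = sp + (size_t)j * n;
    for (int i = 0; i < n; ++i) {
      double p = (gc[i] > 0) ? std::exp(sc[i] - m(i)) : 0.0;
      sc[i] = p;
      s(i) += p;
    }
  }
  for (int j = 0; j < n; ++j) {
    double* sc = sp + (size_t)j * n;
    for (int i = 0; i < n; ++i) sc[i] /= s(i);
  }
}

// forward of one block; returns output, caches and updated BN running stats
// [[Rcpp::export]]
List cpp_block_forward(const arma::mat& h_in, const arma::mat& ghat,
                       const arma::mat& Wq, const arma::mat& Wk,
                       const arma::mat& Wv,
                       const arma::vec& bn1_gamma, const arma::vec& bn1_beta,
                       const arma::mat& W1, const arma::vec& b1,
                       const arma::mat& W2, const arma::vec& b2,
                       const arma::vec& bn2_gamma, const arma::vec& bn2_beta,
                       int n_heads, int d_k, double scale, bool literal_ffn,
                       bool training,
                       const arma::vec& bn1_mean, const arma::vec& bn1_var,
                       const arma::vec& bn2_mean, const arma::vec& bn2_var,
                       double momentum, double bn_eps,
                       Rcpp::Nullable<Rcpp::NumericMatrix> drop_mask) {
  const int n = h_in.n_rows;
  const int dh = h_in.n_cols;
  mat Q = h_in * Wq, K = h_in * Wk, V = h_in * Wv;
  mat a(n, dh, fill::zeros);
  cube P(n, n, n_heads);
  for (int h = 0; h < n_heads; ++h) {
    span idx(h * d_k, (h + 1) * d_k - 1);
    mat S = Q.cols(idx) * K.cols(idx).t();
    if (scale != 1.0) S *= scale;
    S %= ghat;
    masked_softmax(S, ghat);
    P.slice(h) = S;
    a.cols(idx) = S * V.cols(idx);
  }
  if (drop_mask.isNotNull()) a %= Rcpp::as<mat>(drop_mask);
  mat z = a + h_in;

  // BN1
  rowvec mu1, va1;
  vec new_bn1_mean = bn1_mean, new_bn1_var = bn1_var;
  if (training) {
    mu1 = mean(z, 0);
    rowvec m2 = mean(square(z), 0);
    va1 = m2 - square(mu1);
    double unb = (n > 1) ? (double)n / (n - 1) : 1.0;
    new_bn1_mean = (1 - momentum) * bn1_mean + momentum * mu1.t();
    new_bn1_var = (1 - momentum) * bn1_var + momentum * (va1.t() * unb);
  } else {
    mu1 = bn1_mean.t();
    va1 = bn1_var.t();
  }
  rowvec invstd1 = 1.0 / sqrt(va1 + bn_eps);
  mat xhat1 = z;
  xhat1.each_row() -= mu1;
  xhat1.each_row() %= invstd1;
  mat y = xhat1;
  y.each_row() %= bn1_gamma.t();
  y.each_row() += bn1_beta.t();

  // FFN
  mat a1 = y * W1;
  a1.each_row() += b1.t();
  mat r1 = clamp(a1, 0.0, datum::inf);
  mat f = r1 * W2;
  f.each_row() += b2.t();

  mat h_out;
  mat xhat2;
  rowvec invstd2;
  vec new_bn2_mean = bn2_mean, new_bn2_var = bn2_var;
  if (literal_ffn) {
    h_out = f;
  } else {
    mat z2 = f + y;
    rowvec mu2, va2;
    if (training) {
      mu2 = mean(z2, 0);
      rowvec m2 = mean(square(z2), 0);
      va2 = m2 - square(mu2);
      double unb = (n > 1) ? (double)n / (n - 1) : 1.0;
      new_bn2_mean = (1 - momentum) * bn2_mean + momentum * mu2.t();
      new_bn2_var = (1 - momentum) * bn2_var + momentum * (va2.t() * unb);
    } else {
      mu2 = bn2_mean.t();
      va2 = bn2_var.t();
    }
    invstd2 = 1.0 / sqrt(va2 + bn_eps);
    xhat2 = z2;
    xhat2.each_row() -= mu2;
    xhat2.each_row() %= invstd2;
    h_out = xhat2;
    h_out.each_row() %= bn2_gamma.t();
    h_out.each_row() += bn2_beta.t();
  }
  return List::create(
      Named("h") = h_out, Named("P") = P, Named("Q") = Q, Named("K") = K,
      Named("V") = V, Named("xhat1") = xhat1, Named("invstd1") = invstd1.t(),
      Named("y") = y, Named("r1") = r1, Named("xhat2") = xhat2,
      Named("invstd2") = (literal_ffn ? vec() : vec(invstd2.t())),
      Named("bn1_mean") = new_bn1_mean, Named("bn1_var") = new_bn1_var,
      Named("bn2_mean") = new_bn2_mean, Named("bn2_var") = new_bn2_var);
}
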