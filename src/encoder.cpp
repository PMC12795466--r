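// Whole-encoder kernels with edge-sparse attention. The cellular neighbor
// graph is passed in CSR form (row_ptr, col_idx, normalized adjacency
// values including self-loops), so attention logits, softmax and
// aggregation cost O(m * d_k) with m = number of directed edges, rather
// than O(n^2 * d_k). The forward pass keeps all per-layer caches in a C++
// object behind an external pointer; the backward pass reads the cache and
// returns parameter gradients shaped like the R parameter list.
// cpp_encoder_cache_free() releases the cache once gradients are taken.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;
using Rcpp::List;
using Rcpp::Named;

namespace {

struct LayerCache {
  mat Qt, Kt, Vt; // d_h x n (feature-major so per-node head slices are contiguous)
  mat P;          // m x n_heads edge softmax weights
  mat xhat1;
  vec invstd1;
  mat y, r1;
  mat xhat2;
  vec invstd2;
  mat h_in;
  mat drop_mask;
  bool has_drop = false;
};

struct LayerW {
  mat Wq, Wk, Wv, W1, W2;
  vec bn1g, bn1b, b1, b2, bn2g, bn2b;
};

struct EncCache {
  mat X;
  mat relu_mask;
  uvec row_ptr, col_idx;
  vec gvals;
  mat W_proj;
  std::vector<LayerW> w;
  std::vector<LayerCache> layers;
  bool training = true, literal = true;
  double scale = 1.0;
  int n_heads = 1, d_k = 1;
  bool freed = false;
};

mat bn_bwd(const mat& dy, const mat& xhat, const vec& invstd, const vec& gamma,
           bool training, vec& dgamma, vec& dbeta) {
  const int n = dy.n_rows;
  dgamma = sum(dy % xhat, 0).t();
  dbeta = sum(dy, 0).t();
  mat dxhat = dy;
  dxhat.each_row() %= gamma.t();
  if (!training) {
    dxhat.each_row() %= invstd.t();
    return dxhat;
  }
  rowvec s1 = sum(dxhat, 0);
  rowvec s2 = sum(dxhat % xhat, 0);
  mat dz = (double)n * dxhat;
  dz.each_row() -= s1;
  dz -= xhat.each_row() % s2;
  dz.each_row() %= (invstd.t() / n);
  return dz;
}

// edge-sparse multi-head attention forward over feature-major (d_h x n)
// inputs: fills `at` (d_h x n) and the per-head edge softmax matrix P (m x H)
void attn_sparse_fwd(const mat& Qt, const mat& Kt, const mat& Vt,
                     const uvec& rp, const uvec& ci, const vec& gv,
                     int n_heads, int d_k, double scale, mat& at, mat& P) {
  const int n = Qt.n_cols;
  for (int h = 0; h < n_heads; ++h) {
    const int c0 = h * d_k;
    double* p = P.colptr(h);
    for (int i = 0; i < n; ++i) {
      const uword e0 = rp(i), e1 = rp(i + 1);
      const double* qi = Qt.colptr(i) + c0;
      double m = 0.0;
      for (uword e = e0; e < e1; ++e) {
        const double* kj = Kt.colptr(ci(e)) + c0;
        double s = 0.0;
        for (int c = 0; c < d_k; ++c) s += qi[c] * kj[c];
        s *= gv(e) * scale;
        p[e] = s;
        if (s > m) m = s;
      }
      double z = 0.0;
      for (uword e = e0; e < e1; ++e) {
        double w = std::exp(p[e] - m);
        p[e] = w;
        z += w;
      }
      double* ai = at.colptr(i) + c0;
      for (uword e = e0; e < e1; ++e) {
        p[e] /= z;
        const double* vj = Vt.colptr(ci(e)) + c0;
        const double pe = p[e];
        for (int c = 0; c < d_k; ++c) ai[c] += pe * vj[c];
      }
    }
  }
}

// edge-sparse attention backward (feature-major): accumulates the gradient
// blocks [dQt; dKt; dVt] stacked in dQKVt (3 d_h x n) from dat (d_h x n)
void attn_sparse_bwd(const mat& dat, const mat& Qt, const mat& Kt,
                     const mat& Vt, const mat& P, const uvec& rp,
                     const uvec& ci, const vec& gv, int n_heads, int d_k,
                     double scale, mat& dQKVt) {
  const int n = Qt.n_cols;
  const int dh = Qt.n_rows;
  const uword m_edges = ci.n_elem;
  vec dP(m_edges);
  for (int h = 0; h < n_heads; ++h) {
    const int c0 = h * d_k;
    const double* p = P.colptr(h);
    for (int i = 0; i < n; ++i) {
      const uword e0 = rp(i), e1 = rp(i + 1);
      const double* dai = dat.colptr(i) + c0;
      const double* qi = Qt.colptr(i) + c0;
      double rs = 0.0;
      for (uword e = e0; e < e1; ++e) {
        const double* vj = Vt.colptr(ci(e)) + c0;
        double d = 0.0;
        for (int c = 0; c < d_k; ++c) d += dai[c] * vj[c];
        dP(e) = d;
        rs += p[e] * d;
      }
      double* dqi = dQKVt.colptr(i) + c0;
      for (uword e = e0; e < e1; ++e) {
        const uword j = ci(e);
        const double ds = p[e] * (dP(e) - rs) * gv(e) * scale;
        const double pe = p[e];
        const double* kj = Kt.colptr(j) + c0;
        double* dkj = dQKVt.colptr(j) + dh + c0;
        double* dvj = dQKVt.colptr(j) + 2 * dh + c0;
        for (int c = 0; c < d_k; ++c) {
          dqi[c] += ds * kj[c];
          dkj[c] += ds * qi[c];
          dvj[c] += pe * dai[c];
        }
      }
    }
  }
}

} // namespace

// [[Rcpp::export]]
List cpp_encoder_forward(const arma::mat& X, const arma::uvec& row_ptr,
                         const arma::uvec& col_idx, const arma::vec& gvals,
                         const arma::mat& W_proj, Rcpp::List layers,
                         int n_heads, int d_k, double scale, bool literal_ffn,
                         bool training, Rcpp::List bn_state, double momentum,
                         double bn_eps, Rcpp::Nullable<Rcpp::List> drop_masks) {
  auto* C = new EncCache();
  C->X = X;
  C->row_ptr = row_ptr;
  C->col_idx = col_idx;
  C->gvals = gvals;
  C->W_proj = W_proj;
  C->training = training;
  C->literal = literal_ffn;
  C->scale = scale;
  C->n_heads = n_heads;
  C->d_k = d_k;
  const int n = X.n_rows;
  const uword m_edges = col_idx.n_elem;
  const int L = layers.size();
  mat H = X * W_proj;
  C->relu_mask = conv_to<mat>::from(H > 0);
  H = clamp(H, 0.0, datum::inf);

  List new_state(L);
  for (int l = 0; l < L; ++l) {
    List lw = layers[l];
    LayerW W;
    W.Wq = Rcpp::as<mat>(lw["W_Q"]);
    W.Wk = Rcpp::as<mat>(lw["W_K"]);
    W.Wv = Rcpp::as<mat>(lw["W_V"]);
    W.W1 = Rcpp::as<mat>(lw["W1"]);
    W.W2 = Rcpp::as<mat>(lw["W2"]);
    W.bn1g = Rcpp::as<vec>(lw["bn1_gamma"]);
    W.bn1b = Rcpp::as<vec>(lw["bn1_beta"]);
    W.b1 = Rcpp::as<vec>(lw["b1"]);
    W.b2 = Rcpp::as<vec>(lw["b2"]);
    W.bn2g = Rcpp::as<vec>(lw["bn2_gamma"]);
    W.bn2b = Rcpp::as<vec>(lw["bn2_beta"]);

    List st = bn_state[l];
    vec bn1_mean = Rcpp::as<vec>(st["bn1_mean"]);
    vec bn1_var = Rcpp::as<vec>(st["bn1_var"]);
    vec bn2_mean = Rcpp::as<vec>(st["bn2_mean"]);
    vec bn2_var = Rcpp::as<vec>(st["bn2_var"]);

    LayerCache lc;
    lc.h_in = H;
    const int dh = H.n_cols;
    mat Wqkv = join_rows(W.Wq, join_rows(W.Wk, W.Wv));
    mat QKVt = (H * Wqkv).t(); // feature-major for the edge loops
    lc.Qt = QKVt.rows(0, dh - 1);
    lc.Kt = QKVt.rows(dh, 2 * dh - 1);
    lc.Vt = QKVt.rows(2 * dh, 3 * dh - 1);
    mat at(dh, n, fill::zeros);
    lc.P.set_size(m_edges, n_heads);
    attn_sparse_fwd(lc.Qt, lc.Kt, lc.Vt, row_ptr, col_idx, gvals, n_heads,
                    d_k, scale, at, lc.P);
    mat a = at.t();
    if (drop_masks.isNotNull()) {
      List dm(drop_masks);
      if (l < dm.size() && !Rf_isNull(dm[l])) {
        lc.drop_mask = Rcpp::as<mat>(dm[l]);
        lc.has_drop = true;
        a %= lc.drop_mask;
      }
    }
    mat z = a + H;

    rowvec mu1, va1;
    if (training) {
      mu1 = mean(z, 0);
      va1 = mean(square(z), 0) - square(mu1);
      double unb = (n > 1) ? (double)n / (n - 1) : 1.0;
      bn1_mean = (1 - momentum) * bn1_mean + momentum * mu1.t();
      bn1_var = (1 - momentum) * bn1_var + momentum * (va1.t() * unb);
    } else {
      mu1 = bn1_mean.t();
      va1 = bn1_var.t();
    }
    lc.invstd1 = (1.0 / sqrt(va1 + bn_eps)).t();
    mat xhat1 = z;
    xhat1.each_row() -= mu1;
    xhat1.each_row() %= lc.invstd1.t();
    mat y = xhat1;
    y.each_row() %= W.bn1g.t();
    y.each_row() += W.bn1b.t();
    lc.xhat1 = std::move(xhat1);

    mat a1 = y * W.W1;
    a1.each_row() += W.b1.t();
    mat r1 = clamp(a1, 0.0, datum::inf);
    mat f = r1 * W.W2;
    f.each_row() += W.b2.t();
    lc.y = std::move(y);
    lc.r1 = std::move(r1);

    if (literal_ffn) {
      H = std::move(f);
    } else {
      mat z2 = f + lc.y;
      rowvec mu2, va2;
      if (training) {
        mu2 = mean(z2, 0);
        va2 = mean(square(z2), 0) - square(mu2);
        double unb = (n > 1) ? (double)n / (n - 1) : 1.0;
        bn2_mean = (1 - momentum) * bn2_mean + momentum * mu2.t();
        bn2_var = (1 - momentum) * bn2_var + momentum * (va2.t() * unb);
      } else {
        mu2 = bn2_mean.t();
        va2 = bn2_var.t();
      }
      lc.invstd2 = (1.0 / sqrt(va2 + bn_eps)).t();
      mat xhat2 = z2;
      xhat2.each_row() -= mu2;
      xhat2.each_row() %= lc.invstd2.t();
      H = xhat2;
      H.each_row() %= W.bn2g.t();
      H.each_row() += W.bn2b.t();
      lc.xhat2 = std::move(xhat2);
    }
    C->w.push_back(std::move(W));
    C->layers.push_back(std::move(lc));
    new_state[l] = List::create(
        Named("bn1_mean") = bn1_mean, Named("bn1_var") = bn1_var,
        Named("bn2_mean") = bn2_mean, Named("bn2_var") = bn2_var);
  }
  Rcpp::XPtr<EncCache> ptr(C, true);
  return List::create(Named("h") = H, Named("cache") = ptr,
                      Named("state") = new_state);
}

// [[Rcpp::export]]
List cpp_encoder_backward(SEXP cache_ptr, const arma::mat& dh_out,
                          bool want_dX) {
  Rcpp::XPtr<EncCache> ptr(cache_ptr);
  EncCache* C = ptr.get();
  if (C->freed) Rcpp::stop("encoder cache already released");
  const int L = C->layers.size();
  mat dh = dh_out;
  List layer_grads(L);
  for (int l = L - 1; l >= 0; --l) {
    const LayerCache& lc = C->layers[l];
    const LayerW& W = C->w[l];
    const int n = dh.n_rows;
    const int dhid = dh.n_cols;
    mat df;
    vec dg2, db2v;
    const bool lit = C->literal;
    if (lit) {
      df = dh;
      dg2 = zeros<vec>(dhid);
      db2v = zeros<vec>(dhid);
    } else {
      df = bn_bwd(dh, lc.xhat2, lc.invstd2, W.bn2g, C->training, dg2, db2v);
    }
    mat dr1 = df * W.W2.t();
    mat dW2 = lc.r1.t() * df;
    vec db2 = sum(df, 0).t();
    mat da1 = dr1 % conv_to<mat>::from(lc.r1 > 0);
    mat dW1 = lc.y.t() * da1;
    vec db1 = sum(da1, 0).t();
    mat dy = da1 * W.W1.t();
    if (!lit) dy += df;
    vec dg1, db1v;
    mat dz = bn_bwd(dy, lc.xhat1, lc.invstd1, W.bn1g, C->training, dg1, db1v);
    mat da = dz;
    if (lc.has_drop) da %= lc.drop_mask;

    mat dat = da.t(); // feature-major for the edge loops
    mat dQKVt(3 * dhid, n, fill::zeros);
    attn_sparse_bwd(dat, lc.Qt, lc.Kt, lc.Vt, lc.P, C->row_ptr, C->col_idx,
                    C->gvals, C->n_heads, C->d_k, C->scale, dQKVt);
    mat dWqkvT = dQKVt * lc.h_in; // = (h_in' dQKV)'
    mat Wqkv = join_rows(W.Wq, join_rows(W.Wk, W.Wv));
    layer_grads[l] = List::create(
        Named("W_Q") = mat(dWqkvT.rows(0, dhid - 1).t()),
        Named("W_K") = mat(dWqkvT.rows(dhid, 2 * dhid - 1).t()),
        Named("W_V") = mat(dWqkvT.rows(2 * dhid, 3 * dhid - 1).t()),
        Named("bn1_gamma") = dg1, Named("bn1_beta") = db1v,
        Named("W1") = dW1, Named("b1") = db1, Named("W2") = dW2,
        Named("b2") = db2, Named("bn2_gamma") = dg2,
        Named("bn2_beta") = db2v);
    dh = (Wqkv * dQKVt).t() + dz;
  }
  mat dpre = dh % C->relu_mask;
  mat dW_proj = C->X.t() * dpre;
  return List::create(
      Named("grads") = List::create(Named("W_proj") = dW_proj,
                                    Named("layers") = layer_grads),
      Named("dX") = want_dX ? Rcpp::wrap(mat(dpre * C->W_proj.t()))
                            : R_NilValue);
}

// [[Rcpp::export]]
void cpp_encoder_cache_free(SEXP cache_ptr) {
  Rcpp::XPtr<EncCache> ptr(cache_ptr);
  EncCache* C = ptr.get();
  if (C->freed) return;
  C->layers.clear();
  C->layers.shrink_to_fit();
  C->w.clear();
  C->X.reset();
  C->relu_mask.reset();
  C->freed = true;
}

// Adam update on flattened parameter/gradient/moment vectors, in place.
// [[Rcpp::export]]
void cpp_adam_flat(Rcpp::NumericVector theta, Rcpp::NumericVector grad,
                   Rcpp::NumericVector m, Rcpp::NumericVector v, int t,
                   double lr, double beta1, double beta2, double eps,
                   double weight_decay) {
  const R_xlen_t n = theta.size();
  const double c1 = 1.0 - std::pow(beta1, t);
  const double c2 = 1.0 - std::pow(beta2, t);
  double* th = REAL(theta);
  const double* g0 = REAL(grad);
  double* mm = REAL(m);
  double* vv = REAL(v);
  for (R_xlen_t i = 0; i < n; ++i) {
    double g = g0[i] + weight_decay * th[i];
    mm[i] = beta1 * mm[i] + (1.0 - beta1) * g;
    vv[i] = beta2 * vv[i] + (1.0 - beta2) * g * g;
    th[i] -= lr * (mm[i] / c1) / (std::sqrt(vv[i] / c2) + eps);
  }
}
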