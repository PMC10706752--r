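// Hot inner loops of the network: the per-sample, per-head attention
// products and the elementwise AdamW update. Everything else stays in R;
// these two are the only places where R-level temporaries dominate the
// runtime at training scale.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

// Multi-head self-attention forward for one block.
// Q, K, V are (B*T) x (Hh*dk) with token index fastest within a sample.
// With pdrop > 0, an inverted-dropout mask on the attention probabilities is
// drawn from R's RNG (so runs stay deterministic under set.seed) and returned
// for the backward pass. Returns the concatenated head outputs O, the softmax
// attention probabilities A as a (T, T, Hh*B) cube (slice index h + Hh*b),
// and the mask M (or NULL).
// [[Rcpp::export]]
Rcpp::List attn_forward_cpp(const arma::mat& Q, const arma::mat& K,
                            const arma::mat& V, int B, int T, int Hh, int dk,
                            double pdrop) {
  arma::mat O(Q.n_rows, Q.n_cols, arma::fill::zeros);
  arma::cube A(T, T, (arma::uword)Hh * B);
  arma::cube M;
  const bool drop = pdrop > 0;
  if (drop) {
    M.set_size(T, T, (arma::uword)Hh * B);
    const double keep = 1.0 / (1.0 - pdrop);
    for (arma::uword i = 0; i < M.n_elem; ++i)
      M[i] = (unif_rand() >= pdrop) ? keep : 0.0;
  }
  const double scal = 1.0 / std::sqrt((double)dk);
  for (int b = 0; b < B; ++b) {
    const arma::uword r0 = (arma::uword)b * T, r1 = r0 + T - 1;
    for (int h = 0; h < Hh; ++h) {
      const arma::uword c0 = (arma::uword)h * dk, c1 = c0 + dk - 1;
      arma::mat S = Q.submat(r0, c0, r1, c1) *
        K.submat(r0, c0, r1, c1).t() * scal;
      S.each_col() -= arma::max(S, 1);
      S = arma::exp(S);
      S.each_col() /= arma::sum(S, 1);
      A.slice((arma::uword)h + (arma::uword)Hh * b) = S;
      if (drop) S %= M.slice((arma::uword)h + (arma::uword)Hh * b);
      O.submat(r0, c0, r1, c1) = S * V.submat(r0, c0, r1, c1);
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("O") = O, Rcpp::Named("A") = A,
      Rcpp::Named("M") = drop ? Rcpp::wrap(M) : R_NilValue);
}

// Backward pass matching attn_forward_cpp. `A` holds the softmax
// probabilities (pre-dropout) from the forward pass.
// [[Rcpp::export]]
Rcpp::List attn_backward_cpp(const arma::mat& dO, const arma::mat& Q,
                             const arma::mat& K, const arma::mat& V,
                             const arma::cube& A, int B, int T, int Hh,
                             int dk,
                             Rcpp::Nullable<Rcpp::NumericVector> mask) {
  // `mask` is the (T, T, Hh*B) dropout mask returned by the forward pass
  arma::mat dQ(arma::size(Q), arma::fill::zeros);
  arma::mat dK(arma::size(K), arma::fill::zeros);
  arma::mat dV(arma::size(V), arma::fill::zeros);
  const double scal = 1.0 / std::sqrt((double)dk);
  const double* mp = nullptr;
  Rcpp::NumericVector mvec;
  if (mask.isNotNull()) { mvec = mask.get(); mp = mvec.begin(); }
  for (int b = 0; b < B; ++b) {
    const arma::uword r0 = (arma::uword)b * T, r1 = r0 + T - 1;
    for (int h = 0; h < Hh; ++h) {
      const arma::uword c0 = (arma::uword)h * dk, c1 = c0 + dk - 1;
      const arma::mat& Ah = A.slice((arma::uword)h + (arma::uword)Hh * b);
      const arma::mat dOb = dO.submat(r0, c0, r1, c1);
      arma::mat Ad = Ah;
      arma::mat Mh;
      if (mp) {
        Mh = arma::mat(const_cast<double*>(
            mp + ((size_t)b * Hh + h) * (size_t)T * T), T, T, false, true);
        Ad %= Mh;
      }
      arma::mat dAd = dOb * V.submat(r0, c0, r1, c1).t();
      dV.submat(r0, c0, r1, c1) = Ad.t() * dOb;
      arma::mat dA = mp ? arma::mat(dAd % Mh) : dAd;
      const arma::vec rs = arma::sum(dA % Ah, 1);
      arma::mat dS = (Ah % (dA.each_col() - rs)) * scal;
      dQ.submat(r0, c0, r1, c1) = dS * K.submat(r0, c0, r1, c1);
      dK.submat(r0, c0, r1, c1) = dS.t() * Q.submat(r0, c0, r1, c1);
    }
  }
  return Rcpp::List::create(Rcpp::Named("dQ") = dQ, Rcpp::Named("dK") = dK,
                            Rcpp::Named("dV") = dV);
}

// One AdamW step on a single parameter tensor, in place. The caller owns
// p, m and v exclusively (the training loop deep-copies the parameters
// before its first step). bc1/bc2 are the bias-correction factors
// 1 - beta^t.
// [[Rcpp::export]]
void adamw_step_cpp(Rcpp::NumericVector p, Rcpp::NumericVector m,
                    Rcpp::NumericVector v, const Rcpp::NumericVector g,
                    double lr, double wd, double beta1, double beta2,
                    double eps, double bc1, double bc2, bool decay) {
  const R_xlen_t n = p.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double gi = g[i];
    const double mi = beta1 * m[i] + (1.0 - beta1) * gi;
    const double vi = beta2 * v[i] + (1.0 - beta2) * gi * gi;
    m[i] = mi;
    v[i] = vi;
    double upd = (mi / bc1) / (std::sqrt(vi / bc2) + eps);
    if (decay) upd += wd * p[i];
    p[i] -= lr * upd;
  }
}

// Add a row vector to every row of a matrix, in place. Only ever called on a
// freshly allocated matmul result, so mutation cannot alias user data.
// [[Rcpp::export]]
Rcpp::NumericMatrix addrow_cpp(Rcpp::NumericMatrix M, const
                               Rcpp::NumericVector v) {
  const R_xlen_t n = M.nrow(), k = M.ncol();
  double* p = M.begin();
  for (R_xlen_t j = 0; j < k; ++j) {
    const double vj = v[j];
    for (R_xlen_t i = 0; i < n; ++i) p[j * n + i] += vj;
  }
  return M;
}
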