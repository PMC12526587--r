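// Batched block-diagonal multi-head self-attention kernels.
// Token rows are sample-major: row (b-1)*T + t. Attention runs within each
// sample's T x T block only; heads are column blocks of width d/nh.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static void softmax_rows_inplace(mat &S) {
  for (uword i = 0; i < S.n_rows; ++i) {
    rowvec r = S.row(i);
    r -= r.max();
    r = exp(r);
    S.row(i) = r / accu(r);
  }
}

// [[Rcpp::export(name = ".add_bias_cpp")]]
arma::mat add_bias_cpp(const arma::mat &M, const arma::rowvec &b) {
  arma::mat out = M;
  out.each_row() += b;
  return out;
}

// [[Rcpp::export(name = ".relu_cpp")]]
arma::mat relu_cpp(const arma::mat &M) {
  return arma::clamp(M, 0.0, arma::datum::inf);
}

// [[Rcpp::export(name = ".attn_fwd_cpp")]]
Rcpp::List attn_fwd_cpp(const arma::mat &Q, const arma::mat &K,
                        const arma::mat &V, int B, int T, int nh) {
  const uword d = Q.n_cols, dk = d / nh;
  const double scale = 1.0 / std::sqrt((double)dk);
  mat O(Q.n_rows, d, fill::zeros);
  mat A_all(Q.n_rows, (uword)T * nh, fill::zeros);
  for (int b = 0; b < B; ++b) {
    const uword r0 = (uword)b * T, r1 = r0 + T - 1;
    for (int h = 0; h < nh; ++h) {
      const uword c0 = (uword)h * dk, c1 = c0 + dk - 1;
      mat S = Q.submat(r0, c0, r1, c1) * K.submat(r0, c0, r1, c1).t() * scale;
      softmax_rows_inplace(S);
      A_all.submat(r0, (uword)h * T, r1, (uword)(h + 1) * T - 1) = S;
      O.submat(r0, c0, r1, c1) = S * V.submat(r0, c0, r1, c1);
    }
  }
  return Rcpp::List::create(Rcpp::Named("O") = O, Rcpp::Named("A") = A_all);
}

// [[Rcpp::export(name = ".attn_bwd_cpp")]]
Rcpp::List attn_bwd_cpp(const arma::mat &Q, const arma::mat &K,
                        const arma::mat &V, const arma::mat &A_all,
                        const arma::mat &dO, int B, int T, int nh) {
  const uword d = Q.n_cols, dk = d / nh;
  const double scale = 1.0 / std::sqrt((double)dk);
  mat dQ(Q.n_rows, d, fill::zeros), dK(Q.n_rows, d, fill::zeros),
      dV(Q.n_rows, d, fill::zeros);
  for (int b = 0; b < B; ++b) {
    const uword r0 = (uword)b * T, r1 = r0 + T - 1;
    for (int h = 0; h < nh; ++h) {
      const uword c0 = (uword)h * dk, c1 = c0 + dk - 1;
      const mat A = A_all.submat(r0, (uword)h * T, r1, (uword)(h + 1) * T - 1);
      const mat dOb = dO.submat(r0, c0, r1, c1);
      mat dA = dOb * V.submat(r0, c0, r1, c1).t();
      dV.submat(r0, c0, r1, c1) = A.t() * dOb;
      const colvec rs = sum(A % dA, 1);
      mat dS = A % (dA.each_col() - rs);
      dQ.submat(r0, c0, r1, c1) = dS * K.submat(r0, c0, r1, c1) * scale;
      dK.submat(r0, c0, r1, c1) = dS.t() * Q.submat(r0, c0, r1, c1) * scale;
    }
  }
  return Rcpp::List::create(Rcpp::Named("dQ") = dQ, Rcpp::Named("dK") = dK,
                            Rcpp::Named("dV") = dV);
}
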