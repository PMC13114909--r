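// Batched multi-head self-attention kernels.
//
// Layout contract shared with the R side: sequence activations are stored as
// (n * T) x d matrices with sample-major rows (sample i occupies rows
// i*T .. (i+1)*T - 1, 0-based), and head j occupies columns j*dk .. (j+1)*dk-1.
// The softmaxed attention maps are kept on the C++ side as an external
// pointer to a (T x T x n*h) cube, so the forward pass can hand the exact
// probabilities to the backward pass without copying ~15 MB per call across
// the R boundary.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void row_softmax(arma::mat& S) {
  for (arma::uword r = 0; r < S.n_rows; ++r) {
    double m = S.row(r).max();
    arma::rowvec e = arma::exp(S.row(r) - m);
    S.row(r) = e / arma::accu(e);
  }
}

// [[Rcpp::export]]
List mha_forward_cpp(const arma::mat& Q, const arma::mat& K, const arma::mat& V,
                     int n, int T, int h, int dk) {
  arma::mat O(Q.n_rows, Q.n_cols, arma::fill::zeros);
  XPtr<arma::cube> A(new arma::cube(T, T, (arma::uword)n * h), true);
  const double s = std::sqrt((double)dk);
  for (int i = 0; i < n; ++i) {
    const arma::uword r0 = (arma::uword)i * T, r1 = r0 + T - 1;
    for (int j = 0; j < h; ++j) {
      const arma::uword c0 = (arma::uword)j * dk, c1 = c0 + dk - 1;
      arma::mat S = Q.submat(r0, c0, r1, c1) * K.submat(r0, c0, r1, c1).t() / s;
      row_softmax(S);
      A->slice((arma::uword)i * h + j) = S;
      O.submat(r0, c0, r1, c1) = S * V.submat(r0, c0, r1, c1);
    }
  }
  return List::create(_["O"] = O, _["A"] = A);
}

// [[Rcpp::export]]
List mha_backward_cpp(const arma::mat& dO, const arma::mat& Q,
                      const arma::mat& K, const arma::mat& V,
                      SEXP Aptr, int n, int T, int h, int dk) {
  XPtr<arma::cube> A(Aptr);
  arma::mat dQ(Q.n_rows, Q.n_cols, arma::fill::zeros);
  arma::mat dK(Q.n_rows, Q.n_cols, arma::fill::zeros);
  arma::mat dV(Q.n_rows, Q.n_cols, arma::fill::zeros);
  const double s = std::sqrt((double)dk);
  for (int i = 0; i < n; ++i) {
    const arma::uword r0 = (arma::uword)i * T, r1 = r0 + T - 1;
    for (int j = 0; j < h; ++j) {
      const arma::uword c0 = (arma::uword)j * dk, c1 = c0 + dk - 1;
      const arma::mat& Ai = A->slice((arma::uword)i * h + j);
      arma::mat dOij = dO.submat(r0, c0, r1, c1);
      dV.submat(r0, c0, r1, c1) = Ai.t() * dOij;
      arma::mat dA = dOij * V.submat(r0, c0, r1, c1).t();
      // softmax Jacobian: dS = A o (dA - rowSums(dA o A))
      arma::vec rs = arma::sum(dA % Ai, 1);
      arma::mat dS = Ai % (dA.each_col() - rs);
      dQ.submat(r0, c0, r1, c1) = dS * K.submat(r0, c0, r1, c1) / s;
      dK.submat(r0, c0, r1, c1) = dS.t() * Q.submat(r0, c0, r1, c1) / s;
    }
  }
  return List::create(_["dQ"] = dQ, _["dK"] = dK, _["dV"] = dV);
}

// Row-wise attention map extraction for diagnostics/tests: returns the
// attention matrix of one (sample, head) pair from a forward handle.
// [[Rcpp::export]]
arma::mat mha_get_attention_cpp(SEXP Aptr, int sample, int head, int h) {
  XPtr<arma::cube> A(Aptr);
  return A->slice((arma::uword)sample * h + head);
}
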