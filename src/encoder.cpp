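// Full pre-layer-norm transformer encoder layer (forward + backward) for the
// global branch. One C++ call per layer per batch keeps the hot path free of
// R-level allocation overhead; intermediates live in an external-pointer
// cache shared between the forward and backward passes. Dropout masks are
// drawn from R's RNG so seeded runs stay bit-reproducible.
//
// Layout contract (shared with R): activations are (n*T) x dm matrices with
// sample-major rows; head j occupies columns j*dk .. (j+1)*dk - 1.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double LN_EPS = 1e-5;

struct EncCache {
  arma::mat ln1_xhat, ln1_out, Q, K, V, mh_out, drop1, H2;
  arma::mat ln2_xhat, ln2_out, f1, ffh, drop2;
  arma::cube A;
  arma::vec ln1_invstd, ln2_invstd;
  int n, T, h, dk;
  bool training;
  double p;
};

// row-wise layer norm; fills xhat/invstd, returns g*xhat + b
static arma::mat ln_forward(const arma::mat& x, const arma::rowvec& g,
                            const arma::rowvec& b, arma::mat& xhat,
                            arma::vec& invstd) {
  arma::vec mu = arma::mean(x, 1);
  xhat = x.each_col() - mu;
  invstd = 1.0 / arma::sqrt(arma::mean(arma::square(xhat), 1) + LN_EPS);
  xhat.each_col() %= invstd;
  arma::mat y = xhat.each_row() % g;
  y.each_row() += b;
  return y;
}

// backward through row-wise layer norm; returns dx, accumulates dg/db
static arma::mat ln_backward(const arma::mat& dy, const arma::mat& xhat,
                             const arma::vec& invstd, const arma::rowvec& g,
                             arma::rowvec& dg, arma::rowvec& db) {
  dg = arma::sum(dy % xhat, 0);
  db = arma::sum(dy, 0);
  arma::mat dxhat = dy.each_row() % g;
  arma::vec s1 = arma::mean(dxhat, 1);
  arma::vec s2 = arma::mean(dxhat % xhat, 1);
  arma::mat dx = dxhat.each_col() - s1;
  dx -= xhat.each_col() % s2;
  dx.each_col() %= invstd;
  return dx;
}

// inverted-dropout mask drawn from R's RNG (column-major fill)
static arma::mat draw_mask(arma::uword nr, arma::uword nc, double p) {
  const double keep = 1.0 - p;
  arma::mat m(nr, nc);
  GetRNGstate();
  double* ptr = m.memptr();
  for (arma::uword i = 0; i < nr * nc; ++i) {
    ptr[i] = (unif_rand() < keep) ? 1.0 / keep : 0.0;
  }
  PutRNGstate();
  return m;
}

static void row_softmax_inplace(arma::mat& S) {
  for (arma::uword r = 0; r < S.n_rows; ++r) {
    double m = S.row(r).max();
    arma::rowvec e = arma::exp(S.row(r) - m);
    S.row(r) = e / arma::accu(e);
  }
}

// [[Rcpp::export]]
List enc_layer_forward_cpp(const arma::mat& H, const List& par,
                           int n, int T, int h, int dk,
                           double dropout, bool training) {
  XPtr<EncCache> cc(new EncCache(), true);
  cc->n = n; cc->T = T; cc->h = h; cc->dk = dk;
  cc->training = training; cc->p = dropout;
  const arma::rowvec ln1_g = as<arma::rowvec>(par["ln1_g"]);
  const arma::rowvec ln1_b = as<arma::rowvec>(par["ln1_b"]);
  const arma::mat Wq = as<arma::mat>(par["Wq"]);
  const arma::mat Wk = as<arma::mat>(par["Wk"]);
  const arma::mat Wv = as<arma::mat>(par["Wv"]);
  const arma::mat Wo = as<arma::mat>(par["Wo"]);
  const arma::rowvec bq = as<arma::rowvec>(par["bq"]);
  const arma::rowvec bk = as<arma::rowvec>(par["bk"]);
  const arma::rowvec bv = as<arma::rowvec>(par["bv"]);
  const arma::rowvec bo = as<arma::rowvec>(par["bo"]);
  const arma::rowvec ln2_g = as<arma::rowvec>(par["ln2_g"]);
  const arma::rowvec ln2_b = as<arma::rowvec>(par["ln2_b"]);
  const arma::mat W1 = as<arma::mat>(par["ff1_W"]);
  const arma::rowvec b1 = as<arma::rowvec>(par["ff1_b"]);
  const arma::mat W2 = as<arma::mat>(par["ff2_W"]);
  const arma::rowvec b2 = as<arma::rowvec>(par["ff2_b"]);

  // attention sublayer
  cc->ln1_out = ln_forward(H, ln1_g, ln1_b, cc->ln1_xhat, cc->ln1_invstd);
  cc->Q = cc->ln1_out * Wq; cc->Q.each_row() += bq;
  cc->K = cc->ln1_out * Wk; cc->K.each_row() += bk;
  cc->V = cc->ln1_out * Wv; cc->V.each_row() += bv;
  cc->mh_out.set_size(H.n_rows, H.n_cols);
  cc->A.set_size(T, T, (arma::uword)n * h);
  const double s = std::sqrt((double)dk);
  for (int i = 0; i < n; ++i) {
    const arma::uword r0 = (arma::uword)i * T, r1 = r0 + T - 1;
    for (int j = 0; j < h; ++j) {
      const arma::uword c0 = (arma::uword)j * dk, c1 = c0 + dk - 1;
      arma::mat S = cc->Q.submat(r0, c0, r1, c1) *
        cc->K.submat(r0, c0, r1, c1).t() / s;
      row_softmax_inplace(S);
      cc->A.slice((arma::uword)i * h + j) = S;
      cc->mh_out.submat(r0, c0, r1, c1) = S * cc->V.submat(r0, c0, r1, c1);
    }
  }
  arma::mat att = cc->mh_out * Wo;
  att.each_row() += bo;
  if (training && dropout > 0) {
    cc->drop1 = draw_mask(att.n_rows, att.n_cols, dropout);
    att %= cc->drop1;
  }
  cc->H2 = H + att;

  // feed-forward sublayer
  cc->ln2_out = ln_forward(cc->H2, ln2_g, ln2_b, cc->ln2_xhat,
                           cc->ln2_invstd);
  cc->f1 = cc->ln2_out * W1;
  cc->f1.each_row() += b1;
  cc->ffh = cc->f1;
  cc->ffh.transform([](double v) { return v > 0 ? v : 0.0; });
  if (training && dropout > 0) {
    cc->drop2 = draw_mask(cc->ffh.n_rows, cc->ffh.n_cols, dropout);
    cc->ffh %= cc->drop2;
  }
  arma::mat out = cc->ffh * W2;
  out.each_row() += b2;
  out += cc->H2;
  return List::create(_["y"] = out, _["cache"] = cc);
}

// [[Rcpp::export]]
List enc_layer_backward_cpp(const arma::mat& dH3, SEXP cache,
                            const List& par) {
  XPtr<EncCache> cc(cache);
  const arma::mat Wq = as<arma::mat>(par["Wq"]);
  const arma::mat Wk = as<arma::mat>(par["Wk"]);
  const arma::mat Wv = as<arma::mat>(par["Wv"]);
  const arma::mat Wo = as<arma::mat>(par["Wo"]);
  const arma::mat W1 = as<arma::mat>(par["ff1_W"]);
  const arma::mat W2 = as<arma::mat>(par["ff2_W"]);
  const arma::rowvec ln1_g = as<arma::rowvec>(par["ln1_g"]);
  const arma::rowvec ln2_g = as<arma::rowvec>(par["ln2_g"]);
  const int n = cc->n, T = cc->T, h = cc->h, dk = cc->dk;
  const double s = std::sqrt((double)dk);

  // feed-forward sublayer
  arma::mat dW2 = cc->ffh.t() * dH3;
  arma::rowvec db2 = arma::sum(dH3, 0);
  arma::mat dffh = dH3 * W2.t();
  if (cc->drop2.n_elem) dffh %= cc->drop2;
  arma::mat df1 = dffh;
  df1.elem(arma::find(cc->f1 <= 0)).zeros();
  arma::mat dW1 = cc->ln2_out.t() * df1;
  arma::rowvec db1 = arma::sum(df1, 0);
  arma::mat dln2_out = df1 * W1.t();
  arma::rowvec dln2_g, dln2_b;
  arma::mat dH2 = ln_backward(dln2_out, cc->ln2_xhat, cc->ln2_invstd, ln2_g,
                              dln2_g, dln2_b);
  dH2 += dH3;

  // attention sublayer
  arma::mat datt = dH2;
  if (cc->drop1.n_elem) datt = dH2 % cc->drop1;
  arma::mat dWo = cc->mh_out.t() * datt;
  arma::rowvec dbo = arma::sum(datt, 0);
  arma::mat dmh = datt * Wo.t();
  arma::mat dQ(arma::size(cc->Q), arma::fill::zeros);
  arma::mat dK(arma::size(cc->Q), arma::fill::zeros);
  arma::mat dV(arma::size(cc->Q), arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    const arma::uword r0 = (arma::uword)i * T, r1 = r0 + T - 1;
    for (int j = 0; j < h; ++j) {
      const arma::uword c0 = (arma::uword)j * dk, c1 = c0 + dk - 1;
      const arma::mat& Ai = cc->A.slice((arma::uword)i * h + j);
      arma::mat dOij = dmh.submat(r0, c0, r1, c1);
      dV.submat(r0, c0, r1, c1) = Ai.t() * dOij;
      arma::mat dA = dOij * cc->V.submat(r0, c0, r1, c1).t();
      arma::vec rs = arma::sum(dA % Ai, 1);
      arma::mat dS = Ai % (dA.each_col() - rs);
      dQ.submat(r0, c0, r1, c1) = dS * cc->K.submat(r0, c0, r1, c1) / s;
      dK.submat(r0, c0, r1, c1) = dS.t() * cc->Q.submat(r0, c0, r1, c1) / s;
    }
  }
  arma::mat dWq = cc->ln1_out.t() * dQ;
  arma::mat dWk = cc->ln1_out.t() * dK;
  arma::mat dWv = cc->ln1_out.t() * dV;
  arma::rowvec dbq = arma::sum(dQ, 0);
  arma::rowvec dbk = arma::sum(dK, 0);
  arma::rowvec dbv = arma::sum(dV, 0);
  arma::mat dln1_out = dQ * Wq.t() + dK * Wk.t() + dV * Wv.t();
  arma::rowvec dln1_g, dln1_b;
  arma::mat dH = ln_backward(dln1_out, cc->ln1_xhat, cc->ln1_invstd, ln1_g,
                             dln1_g, dln1_b);
  dH += dH2;
  return List::create(
    _["dx"] = dH,
    _["ln1_g"] = dln1_g, _["ln1_b"] = dln1_b,
    _["Wq"] = dWq, _["bq"] = dbq, _["Wk"] = dWk, _["bk"] = dbk,
    _["Wv"] = dWv, _["bv"] = dbv, _["Wo"] = dWo, _["bo"] = dbo,
    _["ln2_g"] = dln2_g, _["ln2_b"] = dln2_b,
    _["ff1_W"] = dW1, _["ff1_b"] = db1, _["ff2_W"] = dW2, _["ff2_b"] = db2
  );
}
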