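// Small numeric utilities on hot paths.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// In-place row-broadcast bias add: y[i, ] += b. `y` must be a freshly
// allocated matrix owned by the caller (as after `%*%`), so mutating it in
// place is safe and avoids an n x p temporary per dense layer.
// [[Rcpp::export]]
void add_bias_inplace(NumericMatrix y, NumericVector b) {
  const int n = y.nrow(), p = y.ncol();
  if (b.size() != p) stop("bias length mismatch");
  double* ptr = y.begin();
  for (int j = 0; j < p; ++j) {
    const double bj = b[j];
    for (int i = 0; i < n; ++i) ptr[(size_t)j * n + i] += bj;
  }
}
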