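// Elementwise activation kernels (hot path: the attention scorers apply
// these to (batch x positions) x hidden matrices every step).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export(name = ".elu_cpp")]]
arma::mat elu_cpp(const arma::mat& x) {
  arma::mat y = x;
  for (arma::uword i = 0; i < y.n_elem; ++i)
    if (y[i] < 0) y[i] = std::expm1(y[i]);
  return y;
}

// [[Rcpp::export(name = ".elu_grad_cpp")]]
arma::mat elu_grad_cpp(const arma::mat& x) {
  arma::mat g(x.n_rows, x.n_cols);
  for (arma::uword i = 0; i < x.n_elem; ++i)
    g[i] = x[i] < 0 ? std::exp(x[i]) : 1.0;
  return g;
}
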