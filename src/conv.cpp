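// im2col-style gather/scatter for same-length 1-d convolution over
// time-major batches (B rows per time step). Offset j of a size-k kernel
// reads time t + j - 1 - floor((k-1)/2); out-of-range positions are zero.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export(name = ".conv_unfold_cpp")]]
arma::mat conv_unfold_cpp(const arma::mat& Xf, int k, int B, int T) {
  const int Cin = Xf.n_cols;
  const int padL = (k - 1) / 2;
  mat Xc(B * T, k * Cin, fill::zeros);
  for (int j = 0; j < k; ++j) {
    const int s = j - padL;
    const int nt = T - std::abs(s);
    if (nt < 1) continue;
    if (s >= 0) {
      Xc.submat(0, j * Cin, nt * B - 1, (j + 1) * Cin - 1) =
          Xf.rows(s * B, T * B - 1);
    } else {
      Xc.submat((-s) * B, j * Cin, T * B - 1, (j + 1) * Cin - 1) =
          Xf.rows(0, nt * B - 1);
    }
  }
  return Xc;
}

// [[Rcpp::export(name = ".conv_fold_cpp")]]
arma::mat conv_fold_cpp(const arma::mat& dXc, int k, int B, int T, int Cin) {
  const int padL = (k - 1) / 2;
  mat dX(B * T, Cin, fill::zeros);
  for (int j = 0; j < k; ++j) {
    const int s = j - padL;
    const int nt = T - std::abs(s);
    if (nt < 1) continue;
    if (s >= 0) {
      dX.rows(s * B, T * B - 1) +=
          dXc.submat(0, j * Cin, nt * B - 1, (j + 1) * Cin - 1);
    } else {
      dX.rows(0, nt * B - 1) +=
          dXc.submat((-s) * B, j * Cin, T * B - 1, (j + 1) * Cin - 1);
    }
  }
  return dX;
}
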