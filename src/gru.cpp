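// Gated recurrent unit time loop (forward + backprop through time).
//
// Batches are laid out time-major: the input projection Xp is a
// (B*T) x 3H matrix whose row block t (rows (t-1)*B .. t*B-1) holds the
// projected inputs W x_t + b for every sequence in the batch at time t,
// with gate columns ordered [reset | update | candidate]. The recurrence is
//   r_t = sigmoid(Xp_r + U_r h_{t-1})
//   z_t = sigmoid(Xp_z + U_z h_{t-1})
//   n_t = tanh(Xp_n + r_t . (U_n h_{t-1}))
//   h_t = z_t . h_{t-1} + (1 - z_t) . n_t
// Masked (padding) positions carry the previous state through unchanged and
// emit an all-zero output row, so trailing padding never influences live
// positions and outputs at padding are exactly zero. A bidirectional
// encoder calls this twice, the second time on a time-reversed batch.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigmoid_mat(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// [[Rcpp::export(name = ".gru_forward_cpp")]]
Rcpp::List gru_forward_cpp(const arma::mat& Xp, const arma::mat& U,
                           const arma::mat& mask, int B, int T, int H) {
  if (Xp.n_rows != (uword)(B * T) || Xp.n_cols != (uword)(3 * H))
    Rcpp::stop("gru_forward: Xp must be (B*T) x 3H");
  if (U.n_rows != (uword)H || U.n_cols != (uword)(3 * H))
    Rcpp::stop("gru_forward: U must be H x 3H");

  mat out(B * T, H), hprev(B * T, H), rs(B * T, H), zs(B * T, H),
      ns(B * T, H), hun(B * T, H);
  mat h(B, H, fill::zeros);

  for (int t = 0; t < T; ++t) {
    const uword r0 = (uword)t * B, r1 = r0 + B - 1;
    hprev.rows(r0, r1) = h;
    mat Hu = h * U;                              // B x 3H
    mat r = sigmoid_mat(Xp.submat(r0, 0, r1, H - 1) + Hu.cols(0, H - 1));
    mat z = sigmoid_mat(Xp.submat(r0, H, r1, 2 * H - 1) + Hu.cols(H, 2 * H - 1));
    mat hu = Hu.cols(2 * H, 3 * H - 1);
    mat n = tanh(Xp.submat(r0, 2 * H, r1, 3 * H - 1) + r % hu);
    mat hnew = z % h + (1.0 - z) % n;
    vec m = mask.col(t);
    h = hnew.each_col() % m + h.each_col() % (1.0 - m);
    out.rows(r0, r1) = hnew.each_col() % m;
    rs.rows(r0, r1) = r;
    zs.rows(r0, r1) = z;
    ns.rows(r0, r1) = n;
    hun.rows(r0, r1) = hu;
  }
  return Rcpp::List::create(
      Rcpp::Named("out") = out, Rcpp::Named("hprev") = hprev,
      Rcpp::Named("r") = rs, Rcpp::Named("z") = zs, Rcpp::Named("n") = ns,
      Rcpp::Named("hun") = hun);
}

// [[Rcpp::export(name = ".gru_backward_cpp")]]
Rcpp::List gru_backward_cpp(const arma::mat& dOut, const arma::mat& hprev,
                            const arma::mat& rs, const arma::mat& zs,
                            const arma::mat& ns, const arma::mat& hun,
                            const arma::mat& U, const arma::mat& mask,
                            int B, int T, int H) {
  mat dXp(B * T, 3 * H, fill::zeros);
  mat dU(H, 3 * H, fill::zeros);
  mat dh(B, H, fill::zeros);

  for (int t = T - 1; t >= 0; --t) {
    const uword r0 = (uword)t * B, r1 = r0 + B - 1;
    vec m = mask.col(t);
    mat dOut_t = dOut.rows(r0, r1);
    dh += dOut_t.each_col() % m;                 // output only emitted when live
    mat dh_new = dh.each_col() % m;              // live: gradient enters the cell
    mat dh_carry = dh.each_col() % (1.0 - m);    // padded: state carried through
    mat hp = hprev.rows(r0, r1);
    mat r = rs.rows(r0, r1), z = zs.rows(r0, r1), n = ns.rows(r0, r1),
        hu = hun.rows(r0, r1);
    mat dz = dh_new % (hp - n);
    mat dn = dh_new % (1.0 - z);
    mat dhp = dh_new % z + dh_carry;
    mat dan = dn % (1.0 - n % n);                // through tanh
    mat dr = dan % hu;
    mat dhu = dan % r;
    mat dar = dr % r % (1.0 - r);                // through sigmoid
    mat daz = dz % z % (1.0 - z);
    dXp.submat(r0, 0, r1, H - 1) = dar;
    dXp.submat(r0, H, r1, 2 * H - 1) = daz;
    dXp.submat(r0, 2 * H, r1, 3 * H - 1) = dan;
    mat dHu = join_rows(dar, daz, dhu);          // B x 3H
    dhp += dHu * U.t();
    dU += hp.t() * dHu;
    dh = dhp;
  }
  return Rcpp::List::create(Rcpp::Named("dXp") = dXp, Rcpp::Named("dU") = dU);
}
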