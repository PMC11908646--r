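// Per-timestep GRU recurrence (forward and backward-through-time).
// The input-side projections (x W + b) are precomputed in R as one wide
// matrix product; only the sequential recurrent part lives here.
//
// Layout: sequences are stacked as (B*T) x h matrices, time-major blocks
// of B rows (rows t*B .. (t+1)*B-1 hold timestep t for all samples).
//
// Gate convention (std_gates = false, as printed in the model spec):
//   M_t = z_t * M_{t-1} + (1 - z_t) * Mtil_t
// std_gates = true uses the textbook roles (z and 1-z swapped).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export]]
Rcpp::List gru_fwd_core(const arma::mat& Az, const arma::mat& Ar,
                        const arma::mat& Am, const arma::mat& Uz,
                        const arma::mat& Ur, const arma::mat& Um,
                        int B, int T, bool std_gates) {
  const int h = Az.n_cols;
  mat Z(B * T, h), R(B * T, h), Htil(B * T, h), UmM(B * T, h), M(B * T, h);
  mat Mprev(B, h, fill::zeros);
  mat z(B, h), r(B, h), umm(B, h), htil(B, h), Mt(B, h);
  for (int t = 0; t < T; ++t) {
    span rows(t * B, (t + 1) * B - 1);
    z = 1.0 / (1.0 + exp(-(Az.rows(rows) + Mprev * Uz)));
    r = 1.0 / (1.0 + exp(-(Ar.rows(rows) + Mprev * Ur)));
    umm = Mprev * Um;
    htil = tanh(Am.rows(rows) + r % umm);
    if (std_gates) Mt = (1.0 - z) % Mprev + z % htil;
    else Mt = z % Mprev + (1.0 - z) % htil;
    Z.rows(rows) = z;
    R.rows(rows) = r;
    Htil.rows(rows) = htil;
    UmM.rows(rows) = umm;
    M.rows(rows) = Mt;
    Mprev = Mt;
  }
  return Rcpp::List::create(Rcpp::Named("M") = M, Rcpp::Named("Z") = Z,
                            Rcpp::Named("R") = R, Rcpp::Named("Htil") = Htil,
                            Rcpp::Named("UmM") = UmM);
}

// Returns the pre-activation gradients dAz, dAr, dAm and dAmr (= da_m % r,
// the factor multiplying U(m)^T and M_{t-1}); weight gradients are formed
// in R by crossprod with the stacked inputs.
// [[Rcpp::export]]
Rcpp::List gru_bwd_core(const arma::mat& dM, const arma::mat& M,
                        const arma::mat& Z, const arma::mat& R,
                        const arma::mat& Htil, const arma::mat& UmM,
                        const arma::mat& Uz, const arma::mat& Ur,
                        const arma::mat& Um, int B, int T, bool std_gates) {
  const int h = dM.n_cols;
  mat dAz(B * T, h), dAr(B * T, h), dAm(B * T, h), dAmr(B * T, h);
  mat dMcarry(B, h, fill::zeros);
  const mat tUz = Uz.t(), tUr = Ur.t(), tUm = Um.t();
  mat dMt(B, h), Mprev(B, h), z(B, h), r(B, h), htil(B, h);
  mat dz(B, h), dhtil(B, h), dMprev(B, h), da_m(B, h), dr(B, h);
  mat da_z(B, h), da_r(B, h), da_mr(B, h);
  for (int t = T - 1; t >= 0; --t) {
    span rows(t * B, (t + 1) * B - 1);
    dMt = dM.rows(rows) + dMcarry;
    if (t > 0) Mprev = M.rows(span((t - 1) * B, t * B - 1));
    else Mprev.zeros();
    z = Z.rows(rows);
    r = R.rows(rows);
    htil = Htil.rows(rows);
    if (std_gates) {
      dz = dMt % (htil - Mprev);
      dhtil = dMt % z;
      dMprev = dMt % (1.0 - z);
    } else {
      dz = dMt % (Mprev - htil);
      dhtil = dMt % (1.0 - z);
      dMprev = dMt % z;
    }
    da_m = dhtil % (1.0 - htil % htil);
    dr = da_m % UmM.rows(rows);
    da_z = dz % z % (1.0 - z);
    da_r = dr % r % (1.0 - r);
    da_mr = da_m % r;
    dAz.rows(rows) = da_z;
    dAr.rows(rows) = da_r;
    dAm.rows(rows) = da_m;
    dAmr.rows(rows) = da_mr;
    dMcarry = dMprev + da_z * tUz + da_r * tUr + da_mr * tUm;
  }
  return Rcpp::List::create(Rcpp::Named("dAz") = dAz,
                            Rcpp::Named("dAr") = dAr,
                            Rcpp::Named("dAm") = dAm,
                            Rcpp::Named("dAmr") = dAmr);
}

// Per-sample multi-head attention scores on stacked (B*T) x d matrices
// (time-major blocks of B rows). Projections happen in R as wide
// products; this computes softmax(Q Kt / sqrt(dh)) V per sample and
// head. Attention weights are returned stacked in (b, h)-major blocks
// of T rows for the backward pass.

// [[Rcpp::export]]
Rcpp::List att_scores_fwd(const arma::mat& Q, const arma::mat& K,
                          const arma::mat& V, int B, int T, int heads) {
  const int d = Q.n_cols;
  const int dh = d / heads;
  const double scale = 1.0 / std::sqrt((double) dh);
  mat A(B * T, d), Wall(B * heads * T, T);
  uvec idx(T);
  mat S(T, T);
  for (int b = 0; b < B; ++b) {
    for (int t = 0; t < T; ++t) idx[t] = b + t * B;
    for (int h = 0; h < heads; ++h) {
      span cols(h * dh, (h + 1) * dh - 1);
      mat Qb = Q.submat(idx, regspace<uvec>(h * dh, (h + 1) * dh - 1));
      mat Kb = K.submat(idx, regspace<uvec>(h * dh, (h + 1) * dh - 1));
      mat Vb = V.submat(idx, regspace<uvec>(h * dh, (h + 1) * dh - 1));
      S = Qb * Kb.t() * scale;
      S.each_col() -= max(S, 1);
      S = exp(S);
      S.each_col() /= sum(S, 1);
      Wall.rows(span((b * heads + h) * T, (b * heads + h + 1) * T - 1)) = S;
      mat Ab = S * Vb;
      for (int t = 0; t < T; ++t) A(idx[t], cols) = Ab.row(t);
    }
  }
  return Rcpp::List::create(Rcpp::Named("A") = A, Rcpp::Named("W") = Wall);
}

// [[Rcpp::export]]
Rcpp::List att_scores_bwd(const arma::mat& dA, const arma::mat& Q,
                          const arma::mat& K, const arma::mat& V,
                          const arma::mat& Wall, int B, int T, int heads) {
  const int d = Q.n_cols;
  const int dh = d / heads;
  const double scale = 1.0 / std::sqrt((double) dh);
  mat dQ(B * T, d, fill::zeros), dK(B * T, d, fill::zeros),
      dV(B * T, d, fill::zeros);
  uvec idx(T);
  for (int b = 0; b < B; ++b) {
    for (int t = 0; t < T; ++t) idx[t] = b + t * B;
    for (int h = 0; h < heads; ++h) {
      span cols(h * dh, (h + 1) * dh - 1);
      uvec ucols = regspace<uvec>(h * dh, (h + 1) * dh - 1);
      mat Qb = Q.submat(idx, ucols);
      mat Kb = K.submat(idx, ucols);
      mat Vb = V.submat(idx, ucols);
      mat dAb = dA.submat(idx, ucols);
      const mat& W = Wall.rows(span((b * heads + h) * T,
                                    (b * heads + h + 1) * T - 1));
      mat dW = dAb * Vb.t();
      mat dVb = W.t() * dAb;
      // softmax backward row-wise
      mat tmp = dW;
      tmp.each_col() -= sum(dW % W, 1);
      mat dS = W % tmp;
      mat dQb = dS * Kb * scale;
      mat dKb = dS.t() * Qb * scale;
      for (int t = 0; t < T; ++t) {
        dQ(idx[t], cols) = dQb.row(t);
        dK(idx[t], cols) = dKb.row(t);
        dV(idx[t], cols) = dVb.row(t);
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dQ") = dQ, Rcpp::Named("dK") = dK,
                            Rcpp::Named("dV") = dV);
}
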