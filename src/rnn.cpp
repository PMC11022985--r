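// Time loops of the recurrent layers. The input projection XW = X * Wx + b
// is done in R as one large BLAS product; these kernels run the per-timestep
// recurrence (forward) and backpropagation-through-time (backward) over the
// stacked (B*T) x units layout, where rows ((t-1)*B, ..., t*B-1) hold
// timestep t. Masking: position t of sample b is live iff maskv[(t-1)*B+b]
// is 1; dead positions carry the previous state through unchanged and emit
// zero output.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// kind: 0 = GRU (gate order z, r, n), 1 = LSTM (gate order i, f, g, o)

// [[Rcpp::export]]
Rcpp::List rnn_fwd_cpp(arma::mat XW, const arma::mat& Wh, const arma::vec& b,
                       const arma::vec& maskv, int B, int T, int kind) {
  const int u = Wh.n_rows;
  XW.each_row() += b.t();
  mat O(B * T, u, fill::zeros);
  mat H(B, u, fill::zeros);
  if (kind == 0) {
    mat Z(B * T, u), R(B * T, u), N(B * T, u), Hprev(B * T, u);
    const mat Whzr = Wh.cols(0, 2 * u - 1);
    const mat Whn = Wh.cols(2 * u, 3 * u - 1);
    for (int t = 0; t < T; ++t) {
      const int r0 = t * B, r1 = (t + 1) * B - 1;
      const vec m = maskv.subvec(r0, r1);
      const mat zr = sigm(XW.submat(r0, 0, r1, 2 * u - 1) + H * Whzr);
      const mat z = zr.cols(0, u - 1);
      const mat r = zr.cols(u, 2 * u - 1);
      const mat n = tanh(XW.submat(r0, 2 * u, r1, 3 * u - 1) + (r % H) * Whn);
      Hprev.rows(r0, r1) = H;
      Z.rows(r0, r1) = z;
      R.rows(r0, r1) = r;
      N.rows(r0, r1) = n;
      const mat hnew = z % H + (1.0 - z) % n;
      H = hnew.each_col() % m + H.each_col() % (1.0 - m);
      O.rows(r0, r1) = H.each_col() % m;
    }
    return Rcpp::List::create(Rcpp::Named("O") = O, Rcpp::Named("Hlast") = H,
                              Rcpp::Named("Z") = Z, Rcpp::Named("R") = R,
                              Rcpp::Named("N") = N, Rcpp::Named("Hprev") = Hprev);
  }
  mat I(B * T, u), F(B * T, u), G(B * T, u), Og(B * T, u);
  mat Cprev(B * T, u), Hprev(B * T, u), Cnew(B * T, u);
  mat C(B, u, fill::zeros);
  for (int t = 0; t < T; ++t) {
    const int r0 = t * B, r1 = (t + 1) * B - 1;
    const vec m = maskv.subvec(r0, r1);
    const mat pre = XW.rows(r0, r1) + H * Wh;
    const mat i = sigm(pre.cols(0, u - 1));
    const mat f = sigm(pre.cols(u, 2 * u - 1));
    const mat g = tanh(pre.cols(2 * u, 3 * u - 1));
    const mat o = sigm(pre.cols(3 * u, 4 * u - 1));
    const mat cn = f % C + i % g;
    const mat hn = o % tanh(cn);
    Cprev.rows(r0, r1) = C;
    Hprev.rows(r0, r1) = H;
    I.rows(r0, r1) = i;
    F.rows(r0, r1) = f;
    G.rows(r0, r1) = g;
    Og.rows(r0, r1) = o;
    Cnew.rows(r0, r1) = cn;
    C = cn.each_col() % m + C.each_col() % (1.0 - m);
    H = hn.each_col() % m + H.each_col() % (1.0 - m);
    O.rows(r0, r1) = H.each_col() % m;
  }
  return Rcpp::List::create(Rcpp::Named("O") = O, Rcpp::Named("Hlast") = H,
                            Rcpp::Named("I") = I, Rcpp::Named("F") = F,
                            Rcpp::Named("G") = G, Rcpp::Named("Og") = Og,
                            Rcpp::Named("Cprev") = Cprev,
                            Rcpp::Named("Hprev") = Hprev,
                            Rcpp::Named("Cnew") = Cnew);
}

// [[Rcpp::export]]
Rcpp::List rnn_bwd_cpp(const arma::mat& Wh, const Rcpp::List& cache,
                       const arma::vec& maskv, const arma::mat& dO,
                       const arma::mat& dHlast, int B, int T, int kind) {
  const int u = Wh.n_rows;
  const int ng = (kind == 0) ? 3 : 4;
  mat dXW(B * T, ng * u, fill::zeros);
  mat dWh(u, ng * u, fill::zeros);
  mat dH = dHlast;
  if (kind == 0) {
    const mat Z = cache["Z"], R = cache["R"], N = cache["N"],
              Hprev = cache["Hprev"];
    const mat Whzr = Wh.cols(0, 2 * u - 1);
    const mat Whn = Wh.cols(2 * u, 3 * u - 1);
    mat dWhzr(u, 2 * u, fill::zeros), dWhn(u, u, fill::zeros);
    for (int t = T - 1; t >= 0; --t) {
      const int r0 = t * B, r1 = (t + 1) * B - 1;
      const vec m = maskv.subvec(r0, r1);
      const mat dOt = dO.rows(r0, r1);
      dH += dOt.each_col() % m;
      const mat z = Z.rows(r0, r1), r = R.rows(r0, r1), n = N.rows(r0, r1);
      const mat hp = Hprev.rows(r0, r1);
      const mat dhnew = dH.each_col() % m;
      mat dHprev = dH.each_col() % (1.0 - m);
      const mat dz = dhnew % (hp - n);
      const mat dn = dhnew % (1.0 - z);
      dHprev += dhnew % z;
      const mat dn_pre = dn % (1.0 - n % n);
      const mat drh = dn_pre * Whn.t();
      dWhn += (r % hp).t() * dn_pre;
      const mat dr = drh % hp;
      dHprev += drh % r;
      const mat dz_pre = dz % z % (1.0 - z);
      const mat dr_pre = dr % r % (1.0 - r);
      const mat dzr_pre = join_rows(dz_pre, dr_pre);
      dWhzr += hp.t() * dzr_pre;
      dHprev += dzr_pre * Whzr.t();
      dXW.submat(r0, 0, r1, 2 * u - 1) = dzr_pre;
      dXW.submat(r0, 2 * u, r1, 3 * u - 1) = dn_pre;
      dH = dHprev;
    }
    dWh = join_rows(dWhzr, dWhn);
    return Rcpp::List::create(Rcpp::Named("dXW") = dXW,
                              Rcpp::Named("dWh") = dWh);
  }
  const mat I = cache["I"], F = cache["F"], G = cache["G"], Og = cache["Og"],
            Cprev = cache["Cprev"], Hprev = cache["Hprev"],
            Cnew = cache["Cnew"];
  mat dC(B, u, fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    const int r0 = t * B, r1 = (t + 1) * B - 1;
    const vec m = maskv.subvec(r0, r1);
    const mat dOt = dO.rows(r0, r1);
    dH += dOt.each_col() % m;
    const mat i = I.rows(r0, r1), f = F.rows(r0, r1), g = G.rows(r0, r1),
              o = Og.rows(r0, r1);
    const mat cp = Cprev.rows(r0, r1), hp = Hprev.rows(r0, r1),
              cn = Cnew.rows(r0, r1);
    const mat tc = tanh(cn);
    const mat dhnew = dH.each_col() % m;
    mat dHprev = dH.each_col() % (1.0 - m);
    mat dCnew = dC.each_col() % m;
    mat dCprev = dC.each_col() % (1.0 - m);
    const mat do_ = dhnew % tc;
    dCnew += dhnew % o % (1.0 - tc % tc);
    const mat df = dCnew % cp;
    const mat di = dCnew % g;
    const mat dg = dCnew % i;
    dCprev += dCnew % f;
    const mat dpre = join_rows(join_rows(di % i % (1.0 - i), df % f % (1.0 - f)),
                               join_rows(dg % (1.0 - g % g), do_ % o % (1.0 - o)));
    dWh += hp.t() * dpre;
    dHprev += dpre * Wh.t();
    dXW.rows(r0, r1) = dpre;
    dH = dHprev;
    dC = dCprev;
  }
  return Rcpp::List::create(Rcpp::Named("dXW") = dXW, Rcpp::Named("dWh") = dWh);
}
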