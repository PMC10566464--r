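// Dense layer forward/backward kernels for the spin-system GNN.
//
// These mirror the R-level definitions in R/nn-ops.R one-to-one; the R
// wrappers keep the same cache contracts so the backward passes stay
// verifiable against finite differences from R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::rowvec;
using arma::vec;

// [[Rcpp::export]]
arma::mat cpp_lin(const arma::mat& x, const arma::mat& w,
                  const arma::rowvec& b) {
  mat out = x * w;
  out.each_row() += b;
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_gru_fwd(const arma::mat& u, const arma::mat& h,
                       const arma::mat& w_all, const arma::mat& u_zr,
                       const arma::mat& un, const arma::rowvec& b_all) {
  const arma::uword d = h.n_cols;
  mat tu = u * w_all;
  tu.each_row() += b_all;
  mat th = h * u_zr;
  mat z = 1.0 / (1.0 + arma::exp(-(tu.cols(0, d - 1) + th.cols(0, d - 1))));
  mat r = 1.0 / (1.0 + arma::exp(-(tu.cols(d, 2 * d - 1) +
                                   th.cols(d, 2 * d - 1))));
  mat rh = r % h;
  mat nn = arma::tanh(tu.cols(2 * d, 3 * d - 1) + rh * un);
  mat out = (1.0 - z) % nn + z % h;
  return List::create(_["out"] = out, _["z"] = z, _["r"] = r,
                      _["rh"] = rh, _["nn"] = nn);
}

// [[Rcpp::export]]
Rcpp::List cpp_gru_bwd(const arma::mat& dout, const arma::mat& u,
                       const arma::mat& h, const arma::mat& z,
                       const arma::mat& r, const arma::mat& rh,
                       const arma::mat& nn, const arma::mat& w_all,
                       const arma::mat& u_zr, const arma::mat& un) {
  mat dz = dout % (h - nn);
  mat dpn = (dout % (1.0 - z)) % (1.0 - nn % nn);
  mat dh = dout % z;

  mat drh = dpn * un.t();
  mat dun = rh.t() * dpn;

  mat dpr = (drh % h) % (r % (1.0 - r));
  dh += drh % r;
  mat dpz = dz % (z % (1.0 - z));

  mat dtu = arma::join_rows(dpz, dpr, dpn);
  mat du = dtu * w_all.t();
  mat dw_all = u.t() * dtu;
  rowvec db_all = arma::sum(dtu, 0);
  mat dzr = arma::join_rows(dpz, dpr);
  dh += dzr * u_zr.t();
  mat du_zr = h.t() * dzr;

  return List::create(_["du"] = du, _["dh"] = dh, _["dw_all"] = dw_all,
                      _["du_zr"] = du_zr, _["dun"] = dun,
                      _["db_all"] = db_all);
}

// [[Rcpp::export]]
Rcpp::List cpp_ln_fwd(const arma::mat& x, const arma::rowvec& gamma,
                      const arma::rowvec& beta, double eps) {
  vec mu = arma::mean(x, 1);
  mat xc = x.each_col() - mu;
  vec v = arma::mean(arma::square(xc), 1);
  vec inv = 1.0 / arma::sqrt(v + eps);
  mat xhat = xc.each_col() % inv;
  mat out = xhat.each_row() % gamma;
  out.each_row() += beta;
  return List::create(_["out"] = out, _["xhat"] = xhat, _["inv"] = inv);
}

// [[Rcpp::export]]
Rcpp::List cpp_ln_bwd(const arma::mat& dout, const arma::mat& xhat,
                      const arma::vec& inv, const arma::rowvec& gamma) {
  const double d = (double)dout.n_cols;
  mat dxhat = dout.each_row() % gamma;
  vec s1 = arma::sum(dxhat, 1);
  vec s2 = arma::sum(dxhat % xhat, 1);
  mat dx = d * dxhat;
  dx.each_col() -= s1;
  dx -= xhat.each_col() % s2;
  dx.each_col() %= (inv / d);
  rowvec dgamma = arma::sum(dout % xhat, 0);
  rowvec dbeta = arma::sum(dout, 0);
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
Rcpp::List cpp_head_fwd(const arma::mat& x, const arma::mat& w1,
                        const arma::rowvec& b1, const arma::mat& w2,
                        const arma::rowvec& b2, const arma::mat& w3,
                        const arma::rowvec& b3) {
  mat h1 = x * w1;
  h1.each_row() += b1;
  mat r1 = h1 % (h1 > 0.0);
  mat res = x + r1 * w2;
  res.each_row() += b2;
  mat out = res * w3;
  out.each_row() += b3;
  return List::create(_["out"] = out, _["r1"] = r1, _["res"] = res);
}

// [[Rcpp::export]]
Rcpp::List cpp_head_bwd(const arma::mat& dout, const arma::mat& x,
                        const arma::mat& r1, const arma::mat& res,
                        const arma::mat& w1, const arma::mat& w2,
                        const arma::mat& w3) {
  mat dres = dout * w3.t();
  mat dw3 = res.t() * dout;
  rowvec db3 = arma::sum(dout, 0);
  mat dr1 = dres * w2.t();
  mat dw2 = r1.t() * dres;
  rowvec db2 = arma::sum(dres, 0);
  mat dh1 = dr1 % (r1 > 0.0);
  mat dx = dres + dh1 * w1.t();
  mat dw1 = x.t() * dh1;
  rowvec db1 = arma::sum(dh1, 0);
  return List::create(_["dx"] = dx, _["dw1"] = dw1, _["db1"] = db1,
                      _["dw2"] = dw2, _["db2"] = db2, _["dw3"] = dw3,
                      _["db3"] = db3);
}

// Pairwise edge input: rows (i, j) -> xd[i, ] * pw1 + xd[j, ] * pw2 + pb
// [[Rcpp::export]]
arma::mat cpp_pair_fwd(const arma::mat& xd, const arma::mat& pw1,
                       const arma::mat& pw2, const arma::rowvec& pb,
                       const arma::uvec& e_i, const arma::uvec& e_j) {
  mat a = xd * pw1;
  mat b = xd * pw2;
  mat out = a.rows(e_i - 1) + b.rows(e_j - 1);
  out.each_row() += pb;
  return out;
}

// Backward of cpp_pair_fwd: scatter edge gradients onto vertices once,
// then push through both projections.
// [[Rcpp::export]]
Rcpp::List cpp_pair_bwd(const arma::mat& de, const arma::mat& xd,
                        const arma::mat& pw1, const arma::mat& pw2,
                        const arma::uvec& e_i, const arma::uvec& e_j,
                        int m_tot) {
  mat acc_i((arma::uword)m_tot, de.n_cols, arma::fill::zeros);
  mat acc_j((arma::uword)m_tot, de.n_cols, arma::fill::zeros);
  for (arma::uword r = 0; r < de.n_rows; ++r) {
    acc_i.row(e_i(r) - 1) += de.row(r);
    acc_j.row(e_j(r) - 1) += de.row(r);
  }
  mat dx = acc_i * pw1.t() + acc_j * pw2.t();
  mat dw1 = xd.t() * acc_i;
  mat dw2 = xd.t() * acc_j;
  rowvec db = arma::sum(de, 0);
  return List::create(_["dx"] = dx, _["dw1"] = dw1, _["dw2"] = dw2,
                      _["db"] = db);
}

// Symmetrize rows over the transpose permutation: (x + x[perm, ]) / 2
// [[Rcpp::export]]
arma::mat cpp_sym(const arma::mat& x, const arma::uvec& perm) {
  return (x + x.rows(perm - 1)) / 2.0;
}

// [[Rcpp::export]]
Rcpp::List cpp_relu_fwd(const arma::mat& x) {
  arma::umat mask = (x > 0.0);
  mat out = x % mask;
  return List::create(_["out"] = out, _["mask"] = mask);
}

// [[Rcpp::export]]
arma::mat cpp_relu_bwd(const arma::mat& dout, const arma::umat& mask) {
  return dout % mask;
}
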