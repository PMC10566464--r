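// Fused forward/backward for the spin-system GNN.
//
// Mirrors the layer-by-layer R implementation in R/model.R (the reference
// path); intermediates are kept on the C++ side between the forward and
// backward calls via an external pointer, so only inputs, head outputs and
// parameter gradients cross the R boundary.  Equivalence of the two paths
// and gradient correctness are asserted in the test suite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::rowvec;
using arma::sp_mat;
using arma::uvec;
using arma::vec;

namespace {

struct LinCache {
  mat x;  // input
};

struct LnCache {
  mat xhat;
  vec inv;
};

struct GruCache {
  mat z, r, rh, nn;  // u and h are cached by the caller
};

struct HeadCache {
  mat r1, res;  // the input is cached by the caller
};

struct MpCache {
  mat x_in;
  mat cat_m;
  arma::umat relu_mask;
  LnCache ln;
};

struct DecCache {
  mat g_in, xd_in, agg_out;
  GruCache gv;
  arma::umat relu_v;
  LnCache lnv;
  mat xd_new;
  mat e_in;
  GruCache ge;
  mat sym;
  arma::umat relu_e;
  LnCache lne;
};

struct ModelCache {
  mat x;  // batch vertex features
  mat xv0, xd0, g0;
  std::vector<MpCache> mp;
  std::vector<DecCache> dec;
  mat vrep, g_final;
  std::vector<HeadCache> sh, cp;
};

mat lin_fwd(const mat& x, const mat& w, const rowvec& b) {
  mat out = x * w;
  out.each_row() += b;
  return out;
}

mat ln_fwd(const mat& x, const rowvec& gamma, const rowvec& beta,
           LnCache& cache) {
  vec mu = arma::mean(x, 1);
  mat xc = x.each_col() - mu;
  vec v = arma::mean(arma::square(xc), 1);
  cache.inv = 1.0 / arma::sqrt(v + 1e-5);
  cache.xhat = xc.each_col() % cache.inv;
  mat out = cache.xhat.each_row() % gamma;
  out.each_row() += beta;
  return out;
}

mat ln_bwd(const mat& dout, const LnCache& cache, const rowvec& gamma,
           rowvec& dgamma, rowvec& dbeta) {
  const double d = (double)dout.n_cols;
  mat dxhat = dout.each_row() % gamma;
  vec s1 = arma::sum(dxhat, 1);
  vec s2 = arma::sum(dxhat % cache.xhat, 1);
  mat dx = d * dxhat;
  dx.each_col() -= s1;
  dx -= cache.xhat.each_col() % s2;
  dx.each_col() %= (cache.inv / d);
  dgamma = arma::sum(dout % cache.xhat, 0);
  dbeta = arma::sum(dout, 0);
  return dx;
}

mat gru_fwd(const mat& u, const mat& h, const List& p, GruCache& c) {
  const mat w_all = as<mat>(p["w_all"]);
  const mat u_zr = as<mat>(p["u_zr"]);
  const mat un = as<mat>(p["un"]);
  const rowvec b_all = as<rowvec>(p["b_all"]);
  const arma::uword d = h.n_cols;
  mat tu = u * w_all;
  tu.each_row() += b_all;
  mat th = h * u_zr;
  c.z = 1.0 / (1.0 + arma::exp(-(tu.cols(0, d - 1) + th.cols(0, d - 1))));
  c.r = 1.0 / (1.0 + arma::exp(-(tu.cols(d, 2 * d - 1) +
                                 th.cols(d, 2 * d - 1))));
  c.rh = c.r % h;
  c.nn = arma::tanh(tu.cols(2 * d, 3 * d - 1) + c.rh * un);
  return (1.0 - c.z) % c.nn + c.z % h;
}

mat gru_bwd(const mat& dout, const mat& u, const mat& h,
            const GruCache& c, const List& p, mat& dh_out, List& dp) {
  const mat w_all = as<mat>(p["w_all"]);
  const mat u_zr = as<mat>(p["u_zr"]);
  const mat un = as<mat>(p["un"]);
  mat dz = dout % (h - c.nn);
  mat dpn = (dout % (1.0 - c.z)) % (1.0 - c.nn % c.nn);
  mat dh = dout % c.z;
  mat drh = dpn * un.t();
  mat dun = c.rh.t() * dpn;
  mat dpr = (drh % h) % (c.r % (1.0 - c.r));
  dh += drh % c.r;
  mat dpz = dz % (c.z % (1.0 - c.z));
  mat dtu = arma::join_rows(dpz, dpr, dpn);
  mat du = dtu * w_all.t();
  mat dzr = arma::join_rows(dpz, dpr);
  dh += dzr * u_zr.t();
  dp = List::create(_["w_all"] = u.t() * dtu,
                    _["u_zr"] = h.t() * dzr,
                    _["un"] = dun,
                    _["b_all"] = arma::sum(dtu, 0));
  dh_out = dh;
  return du;
}

mat head_fwd(const mat& x, const List& p, HeadCache& c) {
  const mat w1 = as<mat>(p["w1"]);
  const mat w2 = as<mat>(p["w2"]);
  const mat w3 = as<mat>(p["w3"]);
  const rowvec b1 = as<rowvec>(p["b1"]);
  const rowvec b2 = as<rowvec>(p["b2"]);
  const rowvec b3 = as<rowvec>(p["b3"]);
  mat h1 = x * w1;
  h1.each_row() += b1;
  c.r1 = h1 % (h1 > 0.0);
  c.res = x + c.r1 * w2;
  c.res.each_row() += b2;
  mat out = c.res * w3;
  out.each_row() += b3;
  return out;
}

mat head_bwd(const mat& dout, const mat& x, const HeadCache& c,
             const List& p, List& dp) {
  const mat w1 = as<mat>(p["w1"]);
  const mat w2 = as<mat>(p["w2"]);
  const mat w3 = as<mat>(p["w3"]);
  mat dres = dout * w3.t();
  mat dw3 = c.res.t() * dout;
  mat dr1 = dres * w2.t();
  mat dw2 = c.r1.t() * dres;
  mat dh1 = dr1 % (c.r1 > 0.0);
  mat dx = dres + dh1 * w1.t();
  dp = List::create(_["w1"] = x.t() * dh1, _["b1"] = arma::sum(dh1, 0),
                    _["w2"] = dw2, _["b2"] = arma::sum(dres, 0),
                    _["w3"] = dw3, _["b3"] = arma::sum(dout, 0));
  return dx;
}

mat sym_rows(const mat& x, const uvec& perm) {
  return (x + x.rows(perm - 1)) / 2.0;
}

// residual channel coupling: experimental column = ab column + delta
mat couple_fwd(mat out, int n_channels) {
  if (n_channels != 2) return out;
  for (arma::uword c = 0; c + 1 < out.n_cols; c += 2) {
    out.col(c) += out.col(c + 1);
  }
  return out;
}

mat couple_bwd(mat dout, int n_channels) {
  if (n_channels != 2) return dout;
  for (arma::uword c = 0; c + 1 < dout.n_cols; c += 2) {
    dout.col(c + 1) += dout.col(c);
  }
  return dout;
}

// aggregation over the neighbor dimension: configured all-pairs channel
// concatenated with the bonded-neighbor mean channel
mat agg_fwd(const mat& g, const sp_mat& agg, const sp_mat& agg_bond,
            const sp_mat& agg_gem) {
  return arma::join_rows(mat(agg * g), mat(agg_bond * g),
                         mat(agg_gem * g));
}

}  // namespace

// [[Rcpp::export]]
SEXP cpp_model_forward(List params, List batch, List mcfg,
                       bool need_cache) {
  ModelCache* C = new ModelCache();
  const mat x = as<mat>(batch["x"]);
  const mat edge_feat = as<mat>(batch["edge_feat"]);
  const uvec e_i = as<uvec>(batch["e_i"]);
  const uvec e_j = as<uvec>(batch["e_j"]);
  const uvec trans = as<uvec>(batch["trans"]);
  const sp_mat agg = as<sp_mat>(batch["agg_sp"]);
  const sp_mat agg_bond = as<sp_mat>(batch["agg_bond_sp"]);
  const sp_mat agg_gem = as<sp_mat>(batch["agg_gem_sp"]);
  List adj = batch["adj"];
  const int n_mp = as<int>(mcfg["n_message_layers"]);
  const int n_dec = as<int>(mcfg["n_decode_layers"]);
  const int n_boot = as<int>(mcfg["n_bootstraps"]);

  C->x = x;
  List vin = params["vin"], din = params["din"], gin = params["gin"];
  C->xv0 = lin_fwd(x, as<mat>(vin["w"]), as<rowvec>(vin["b"]));
  C->xd0 = lin_fwd(x, as<mat>(din["w"]), as<rowvec>(din["b"]));
  C->g0 = lin_fwd(edge_feat, as<mat>(gin["w"]), as<rowvec>(gin["b"]));

  List mp = params["mp"];
  mat xv = C->xv0;
  C->mp.resize(n_mp);
  const int n_slices = adj.size();
  for (int l = 0; l < n_mp; ++l) {
    List pl = mp[l];
    List lifts = pl["lift"];
    MpCache& mc = C->mp[l];
    mc.x_in = xv;
    const arma::uword dd = xv.n_cols;
    mat cat_m(x.n_rows, n_slices * dd);
    for (int s = 0; s < n_slices; ++s) {
      sp_mat a = as<sp_mat>(adj[s]);
      mat lift = xv * as<mat>(lifts[s]);
      cat_m.cols(s * dd, (s + 1) * dd - 1) = a * lift;
    }
    mc.cat_m = cat_m;
    mat pre = lin_fwd(cat_m, as<mat>(pl["coll"]), as<rowvec>(pl["b"]));
    mc.relu_mask = (pre > 0.0);
    pre = pre % mc.relu_mask;
    List ln = pl["ln"];
    xv = ln_fwd(pre, as<rowvec>(ln["gamma"]), as<rowvec>(ln["beta"]),
                mc.ln);
  }

  List dec = params["dec"];
  mat xd = C->xd0;
  mat g = C->g0;
  C->dec.resize(n_dec);
  for (int l = 0; l < n_dec; ++l) {
    List pl = dec[l];
    DecCache& dc = C->dec[l];
    dc.g_in = g;
    dc.xd_in = xd;
    dc.agg_out = agg_fwd(g, agg, agg_bond, agg_gem);
    mat gv_out = gru_fwd(dc.agg_out, xd, pl["gv"], dc.gv);
    dc.relu_v = (gv_out > 0.0);
    gv_out = gv_out % dc.relu_v;
    List lnv = pl["lnv"];
    dc.xd_new = ln_fwd(gv_out, as<rowvec>(lnv["gamma"]),
                       as<rowvec>(lnv["beta"]), dc.lnv);
    mat a = dc.xd_new * as<mat>(pl["pw1"]);
    mat b = dc.xd_new * as<mat>(pl["pw2"]);
    dc.e_in = a.rows(e_i - 1) + b.rows(e_j - 1);
    dc.e_in.each_row() += as<rowvec>(pl["pb"]);
    mat ge_out = gru_fwd(dc.e_in, g, pl["ge"], dc.ge);
    dc.sym = sym_rows(ge_out, trans);
    dc.relu_e = (dc.sym > 0.0);
    mat pre = dc.sym % dc.relu_e;
    List lne = pl["lne"];
    g = ln_fwd(pre, as<rowvec>(lne["gamma"]), as<rowvec>(lne["beta"]),
               dc.lne);
    xd = dc.xd_new;
  }

  C->vrep = arma::join_rows(xv, xd);
  C->g_final = g;

  List heads = params["heads"];
  List sh_heads = heads["shift"];
  List cp_heads = heads["coupling"];
  C->sh.resize(n_boot);
  C->cp.resize(n_boot);
  const int n_channels =
      as<bool>(mcfg["channel_coupling"]) ? as<int>(mcfg["n_channels"]) : 1;
  List shift_out(n_boot), coupling_out(n_boot);
  for (int b = 0; b < n_boot; ++b) {
    shift_out[b] = couple_fwd(head_fwd(C->vrep, sh_heads[b], C->sh[b]),
                              n_channels);
    mat raw = head_fwd(C->g_final, cp_heads[b], C->cp[b]);
    coupling_out[b] = couple_fwd(sym_rows(raw, trans), n_channels);
  }

  List out = List::create(_["shift"] = shift_out,
                          _["coupling"] = coupling_out);
  if (need_cache) {
    XPtr<ModelCache> ptr(C, true);
    out["handle"] = ptr;
  } else {
    delete C;
    out["handle"] = R_NilValue;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_model_backward(SEXP handle, List params, List batch, List mcfg,
                        List d_shift, List d_coupling) {
  XPtr<ModelCache> C(handle);
  const uvec e_i = as<uvec>(batch["e_i"]);
  const uvec e_j = as<uvec>(batch["e_j"]);
  const uvec trans = as<uvec>(batch["trans"]);
  const sp_mat agg = as<sp_mat>(batch["agg_sp"]);
  const sp_mat agg_bond = as<sp_mat>(batch["agg_bond_sp"]);
  const sp_mat agg_gem = as<sp_mat>(batch["agg_gem_sp"]);
  List adj = batch["adj"];
  const int n_mp = as<int>(mcfg["n_message_layers"]);
  const int n_dec = as<int>(mcfg["n_decode_layers"]);
  const int n_boot = as<int>(mcfg["n_bootstraps"]);
  const int d = as<int>(mcfg["hidden_dim"]);
  const int e_d = as<int>(mcfg["edge_dim"]);
  const arma::uword m_tot = C->x.n_rows;
  const arma::uword e_tot = e_i.n_elem;

  List heads = params["heads"];
  List sh_heads = heads["shift"];
  List cp_heads = heads["coupling"];
  mat dvrep(m_tot, 2 * d, arma::fill::zeros);
  mat dg(e_tot, e_d, arma::fill::zeros);
  List g_sh(n_boot), g_cp(n_boot);
  const int n_channels =
      as<bool>(mcfg["channel_coupling"]) ? as<int>(mcfg["n_channels"]) : 1;
  for (int b = 0; b < n_boot; ++b) {
    if (!Rf_isNull(d_shift[b])) {
      List dp;
      dvrep += head_bwd(couple_bwd(as<mat>(d_shift[b]), n_channels),
                        C->vrep, C->sh[b], sh_heads[b], dp);
      g_sh[b] = dp;
    }
    if (!Rf_isNull(d_coupling[b])) {
      mat draw = sym_rows(couple_bwd(as<mat>(d_coupling[b]), n_channels),
                          trans);
      List dp;
      dg += head_bwd(draw, C->g_final, C->cp[b], cp_heads[b], dp);
      g_cp[b] = dp;
    }
  }

  mat dxv = dvrep.cols(0, d - 1);
  mat dxd = dvrep.cols(d, 2 * d - 1);

  List dec = params["dec"];
  List g_dec(n_dec);
  for (int l = n_dec - 1; l >= 0; --l) {
    List pl = dec[l];
    DecCache& dc = C->dec[l];
    List lne = pl["lne"];
    rowvec dgam_e, dbet_e;
    mat dpre = ln_bwd(dg, dc.lne, as<rowvec>(lne["gamma"]), dgam_e,
                      dbet_e);
    dpre = dpre % dc.relu_e;
    mat dge_out = sym_rows(dpre, trans);
    List dp_ge;
    mat dg_hidden;
    mat de_in = gru_bwd(dge_out, dc.e_in, dc.g_in, dc.ge, pl["ge"],
                        dg_hidden, dp_ge);

    // pair projection backward
    mat acc_i(m_tot, (arma::uword)e_d, arma::fill::zeros);
    mat acc_j(m_tot, (arma::uword)e_d, arma::fill::zeros);
    for (arma::uword r = 0; r < e_tot; ++r) {
      acc_i.row(e_i(r) - 1) += de_in.row(r);
      acc_j.row(e_j(r) - 1) += de_in.row(r);
    }
    mat pw1 = as<mat>(pl["pw1"]);
    mat pw2 = as<mat>(pl["pw2"]);
    mat dxd_total = dxd + acc_i * pw1.t() + acc_j * pw2.t();
    mat dpw1 = dc.xd_new.t() * acc_i;
    mat dpw2 = dc.xd_new.t() * acc_j;
    rowvec dpb = arma::sum(de_in, 0);

    List lnv = pl["lnv"];
    rowvec dgam_v, dbet_v;
    mat dpre_v = ln_bwd(dxd_total, dc.lnv, as<rowvec>(lnv["gamma"]),
                        dgam_v, dbet_v);
    dpre_v = dpre_v % dc.relu_v;
    List dp_gv;
    mat dxd_prev;
    mat du = gru_bwd(dpre_v, dc.agg_out, dc.xd_in, dc.gv, pl["gv"],
                     dxd_prev, dp_gv);
    mat dg_prev = dg_hidden +
      mat(agg.t() * du.cols(0, e_d - 1)) +
      mat(agg_bond.t() * du.cols(e_d, 2 * e_d - 1)) +
      mat(agg_gem.t() * du.cols(2 * e_d, 3 * e_d - 1));

    g_dec[l] = List::create(
        _["gv"] = dp_gv,
        _["lnv"] = List::create(_["gamma"] = dgam_v, _["beta"] = dbet_v),
        _["pw1"] = dpw1, _["pw2"] = dpw2, _["pb"] = dpb,
        _["ge"] = dp_ge,
        _["lne"] = List::create(_["gamma"] = dgam_e, _["beta"] = dbet_e));
    dg = dg_prev;
    dxd = dxd_prev;
  }

  List mp = params["mp"];
  List g_mp(n_mp);
  const int n_slices = adj.size();
  for (int l = n_mp - 1; l >= 0; --l) {
    List pl = mp[l];
    List lifts = pl["lift"];
    MpCache& mc = C->mp[l];
    List ln = pl["ln"];
    rowvec dgam, dbet;
    mat dpre = ln_bwd(dxv, mc.ln, as<rowvec>(ln["gamma"]), dgam, dbet);
    dpre = dpre % mc.relu_mask;
    mat coll = as<mat>(pl["coll"]);
    mat dcat = dpre * coll.t();
    mat dcoll = mc.cat_m.t() * dpre;
    rowvec db = arma::sum(dpre, 0);
    mat dx_in(m_tot, (arma::uword)d, arma::fill::zeros);
    List dlifts(n_slices);
    for (int s = 0; s < n_slices; ++s) {
      sp_mat a = as<sp_mat>(adj[s]);
      mat dmsg = dcat.cols(s * d, (s + 1) * d - 1);
      mat dlift = mat(a.t() * dmsg);
      dlifts[s] = mc.x_in.t() * dlift;
      dx_in += dlift * as<mat>(lifts[s]).t();
    }
    g_mp[l] = List::create(
        _["lift"] = dlifts, _["coll"] = dcoll, _["b"] = db,
        _["ln"] = List::create(_["gamma"] = dgam, _["beta"] = dbet));
    dxv = dx_in;
  }

  List vin = params["vin"], din = params["din"], gin = params["gin"];
  List g_vin = List::create(_["w"] = C->x.t() * dxv,
                            _["b"] = arma::sum(dxv, 0));
  List g_din = List::create(_["w"] = C->x.t() * dxd,
                            _["b"] = arma::sum(dxd, 0));
  const mat edge_feat = as<mat>(batch["edge_feat"]);
  List g_gin = List::create(_["w"] = edge_feat.t() * dg,
                            _["b"] = arma::sum(dg, 0));

  return List::create(
      _["vin"] = g_vin, _["din"] = g_din, _["gin"] = g_gin,
      _["mp"] = g_mp, _["dec"] = g_dec,
      _["heads"] = List::create(_["shift"] = g_sh, _["coupling"] = g_cp));
}
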