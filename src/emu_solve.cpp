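// Hot path of the EMU simulator.  The level systems' structure
// (aggregated cell indices, flux-mapping matrices, condensation
// wiring, tracer inputs) is precompiled on the R side and frozen into
// a C++ object held by an external pointer; each simulation call then
// only passes the per-direction flux vector and the mixing fractions,
// assembles the flux-weighted balance matrices, and solves one dense
// system per EMU size level.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

struct Level {
  int n, size, nk;
  std::vector<int> tcell, bcell;
  arma::mat Tmat, Bmat, kfixed;
  std::vector<int> ktype, p1lev, p1row, p2lev, p2row;
  std::vector<arma::rowvec> pfix1, pfix2;
};

struct OutSpec {
  int kind;              // 0 fixed, 1 direct, 2 mixing combo
  int l1, r1, l2, r2;    // level/row references (0-based)
  int mixidx;            // index into the mixing-fraction vector
  arma::rowvec fixed;
  int len;               // size + 1
};

struct CompiledSystem {
  std::vector<Level> levels;
  std::vector<OutSpec> outs;
  int total_len;
};

static arma::rowvec conv_rows(const arma::rowvec& a, const arma::rowvec& b) {
  arma::rowvec out(a.n_elem + b.n_elem - 1, arma::fill::zeros);
  for (arma::uword i = 0; i < a.n_elem; ++i)
    for (arma::uword j = 0; j < b.n_elem; ++j)
      out(i + j) += a(i) * b(j);
  return out;
}

// [[Rcpp::export]]
SEXP emu_build_cpp(List levels, List outspecs) {
  XPtr<CompiledSystem> ptr(new CompiledSystem, true);
  for (int l = 0; l < levels.size(); ++l) {
    List lv = levels[l];
    Level L;
    L.n = as<int>(lv["n"]);
    L.size = as<int>(lv["size"]);
    L.nk = as<int>(lv["nk"]);
    L.tcell = as<std::vector<int> >(lv["tcell"]);
    L.Tmat = as<arma::mat>(lv["Tmat"]);
    L.bcell = as<std::vector<int> >(lv["bcell"]);
    L.Bmat = as<arma::mat>(lv["Bmat"]);
    L.kfixed = as<arma::mat>(lv["kfixed"]);
    L.ktype = as<std::vector<int> >(lv["ktype"]);
    L.p1lev = as<std::vector<int> >(lv["p1lev"]);
    L.p1row = as<std::vector<int> >(lv["p1row"]);
    L.p2lev = as<std::vector<int> >(lv["p2lev"]);
    L.p2row = as<std::vector<int> >(lv["p2row"]);
    List pf1 = lv["pfix1"], pf2 = lv["pfix2"];
    L.pfix1.resize(L.nk); L.pfix2.resize(L.nk);
    for (int k = 0; k < L.nk; ++k) {
      if (pf1.size() > k && !Rf_isNull(pf1[k]))
        L.pfix1[k] = as<arma::rowvec>(pf1[k]);
      if (pf2.size() > k && !Rf_isNull(pf2[k]))
        L.pfix2[k] = as<arma::rowvec>(pf2[k]);
    }
    ptr->levels.push_back(L);
  }
  int off = 0;
  for (int q = 0; q < outspecs.size(); ++q) {
    List os = outspecs[q];
    OutSpec o;
    o.kind = as<int>(os["kind"]);
    o.l1 = o.r1 = o.l2 = o.r2 = -1; o.mixidx = -1;
    if (o.kind >= 1) { o.l1 = as<int>(os["l1"]); o.r1 = as<int>(os["r1"]); }
    if (o.kind == 2) {
      o.l2 = as<int>(os["l2"]); o.r2 = as<int>(os["r2"]);
      o.mixidx = as<int>(os["mixidx"]);
    }
    if (o.kind == 0) o.fixed = as<arma::rowvec>(os["fixed"]);
    o.len = as<int>(os["len"]);
    off += o.len;
    ptr->outs.push_back(o);
  }
  ptr->total_len = off;
  return ptr;
}

// [[Rcpp::export]]
NumericVector emu_run_cpp(SEXP sysptr, const arma::vec& vdir,
                          const arma::vec& mixing) {
  XPtr<CompiledSystem> ptr(sysptr);
  CompiledSystem& cs = *ptr;
  int nlev = cs.levels.size();
  std::vector<arma::mat> solved(nlev);

  for (int l = 0; l < nlev; ++l) {
    Level& L = cs.levels[l];
    arma::mat M(L.n, L.n, arma::fill::zeros);
    arma::vec tv = L.Tmat * vdir;
    for (size_t i = 0; i < L.tcell.size(); ++i) M(L.tcell[i]) += tv(i);

    arma::mat Y(L.nk, L.size + 1, arma::fill::zeros);
    for (int k = 0; k < L.nk; ++k) {
      if (L.ktype[k] == 0) {
        Y.row(k) = L.kfixed.row(k);
      } else {
        const arma::rowvec& a = (L.p1lev[k] >= 0)
          ? arma::rowvec(solved[L.p1lev[k]].row(L.p1row[k])) : L.pfix1[k];
        const arma::rowvec& b = (L.p2lev[k] >= 0)
          ? arma::rowvec(solved[L.p2lev[k]].row(L.p2row[k])) : L.pfix2[k];
        Y.row(k) = conv_rows(a, b);
      }
    }

    arma::mat B(L.n, L.nk, arma::fill::zeros);
    if (!L.bcell.empty()) {
      arma::vec bv = L.Bmat * vdir;
      for (size_t i = 0; i < L.bcell.size(); ++i) B(L.bcell[i]) += bv(i);
    }

    arma::mat X;
    bool ok = arma::solve(X, M, B * Y, arma::solve_opts::no_approx);
    if (!ok) stop("singular level-%d EMU system", L.size);
    solved[l] = X;
  }

  NumericVector out(cs.total_len);
  int off = 0;
  for (size_t q = 0; q < cs.outs.size(); ++q) {
    OutSpec& o = cs.outs[q];
    if (o.kind == 0) {
      for (int j = 0; j < o.len; ++j) out[off + j] = o.fixed(j);
    } else if (o.kind == 1) {
      const arma::mat& X = solved[o.l1];
      for (int j = 0; j < o.len; ++j) out[off + j] = X(o.r1, j);
    } else {
      double f = mixing(o.mixidx);
      const arma::mat& A = solved[o.l1];
      const arma::mat& B2 = solved[o.l2];
      for (int j = 0; j < o.len; ++j)
        out[off + j] = f * A(o.r1, j) + (1 - f) * B2(o.r2, j);
    }
    off += o.len;
  }
  return out;
}

// Forward-sensitivity variant: solves each level once, then reuses the
// inverse to propagate derivatives of the target MIDs with respect to
// the fit parameters.  dvdir (ndir x npar) and dmix (nmix x npar) are
// the chain-rule derivatives of the per-direction fluxes and mixing
// fractions, computed in R where the kinks (net sign, exchange floor,
// compactification) are handled.
// [[Rcpp::export]]
List emu_run_sens_cpp(SEXP sysptr, const arma::vec& vdir,
                      const arma::vec& mixing, const arma::mat& dvdir,
                      const arma::mat& dmix) {
  XPtr<CompiledSystem> ptr(sysptr);
  CompiledSystem& cs = *ptr;
  int nlev = cs.levels.size();
  int npar = dvdir.n_cols;
  std::vector<arma::mat> solved(nlev);
  std::vector<arma::cube> dsolved(nlev);

  for (int l = 0; l < nlev; ++l) {
    Level& L = cs.levels[l];
    arma::mat M(L.n, L.n, arma::fill::zeros);
    arma::vec tv = L.Tmat * vdir;
    for (size_t i = 0; i < L.tcell.size(); ++i) M(L.tcell[i]) += tv(i);

    arma::mat Y(L.nk, L.size + 1, arma::fill::zeros);
    arma::cube dY(L.nk, L.size + 1, npar, arma::fill::zeros);
    for (int k = 0; k < L.nk; ++k) {
      if (L.ktype[k] == 0) {
        Y.row(k) = L.kfixed.row(k);
      } else {
        arma::rowvec a, b;
        bool a_var = L.p1lev[k] >= 0, b_var = L.p2lev[k] >= 0;
        if (a_var) a = solved[L.p1lev[k]].row(L.p1row[k]);
        else a = L.pfix1[k];
        if (b_var) b = solved[L.p2lev[k]].row(L.p2row[k]);
        else b = L.pfix2[k];
        Y.row(k) = conv_rows(a, b);
        for (int p = 0; p < npar; ++p) {
          arma::rowvec d(Y.n_cols, arma::fill::zeros);
          if (a_var) {
            arma::rowvec da =
              dsolved[L.p1lev[k]].slice(p).row(L.p1row[k]);
            d += conv_rows(da, b);
          }
          if (b_var) {
            arma::rowvec db =
              dsolved[L.p2lev[k]].slice(p).row(L.p2row[k]);
            d += conv_rows(a, db);
          }
          dY.slice(p).row(k) = d;
        }
      }
    }

    arma::mat B(L.n, L.nk, arma::fill::zeros);
    if (!L.bcell.empty()) {
      arma::vec bv = L.Bmat * vdir;
      for (size_t i = 0; i < L.bcell.size(); ++i) B(L.bcell[i]) += bv(i);
    }

    arma::mat Minv;
    if (!arma::inv(Minv, M))
      stop("singular level-%d EMU system", L.size);
    arma::mat X = Minv * (B * Y);
    solved[l] = X;

    arma::cube dX(L.n, L.size + 1, npar);
    for (int p = 0; p < npar; ++p) {
      arma::mat dM(L.n, L.n, arma::fill::zeros);
      arma::vec dtv = L.Tmat * dvdir.col(p);
      for (size_t i = 0; i < L.tcell.size(); ++i) dM(L.tcell[i]) += dtv(i);
      arma::mat dB(L.n, L.nk, arma::fill::zeros);
      if (!L.bcell.empty()) {
        arma::vec dbv = L.Bmat * dvdir.col(p);
        for (size_t i = 0; i < L.bcell.size(); ++i) dB(L.bcell[i]) += dbv(i);
      }
      dX.slice(p) = Minv * (dB * Y + B * dY.slice(p) - dM * X);
    }
    dsolved[l] = dX;
  }

  NumericVector out(cs.total_len);
  NumericMatrix dout(cs.total_len, npar);
  int off = 0;
  for (size_t q = 0; q < cs.outs.size(); ++q) {
    OutSpec& o = cs.outs[q];
    if (o.kind == 0) {
      for (int j = 0; j < o.len; ++j) out[off + j] = o.fixed(j);
    } else if (o.kind == 1) {
      const arma::mat& X = solved[o.l1];
      const arma::cube& dX = dsolved[o.l1];
      for (int j = 0; j < o.len; ++j) {
        out[off + j] = X(o.r1, j);
        for (int p = 0; p < npar; ++p)
          dout(off + j, p) = dX(o.r1, j, p);
      }
    } else {
      double f = mixing(o.mixidx);
      const arma::mat& A = solved[o.l1];
      const arma::mat& B2 = solved[o.l2];
      const arma::cube& dA = dsolved[o.l1];
      const arma::cube& dB2 = dsolved[o.l2];
      for (int j = 0; j < o.len; ++j) {
        out[off + j] = f * A(o.r1, j) + (1 - f) * B2(o.r2, j);
        for (int p = 0; p < npar; ++p)
          dout(off + j, p) = f * dA(o.r1, j, p) +
            (1 - f) * dB2(o.r2, j, p) +
            dmix(o.mixidx, p) * (A(o.r1, j) - B2(o.r2, j));
      }
    }
    off += o.len;
  }
  return List::create(Named("out") = out, Named("dout") = dout);
}
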