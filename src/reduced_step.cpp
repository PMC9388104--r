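// Fixed-step SSPRK3 integrator for the reduced wedge dynamics:
//   dt n_i = (1/H) dx( H Dc dx c_i )                    (flux form)
//   dt c_i = kappa (c_i* - c_i) + (1/H) dx( H Dc dx c_i )
// The auxiliary cytosol field relaxes to the local-equilibria closure
// c_i*(H, nD, nE) AND diffuses: without the diffusion term, laterally
// unstable regions (where dc*/dn has a negative eigenvalue) would grow at
// a rate ~ sqrt(kappa Dc |S|) q, unbounded in the wavenumber q; with it
// the growth saturates at kappa |S| while the large-scale limit
// (effective diffusion Dc dc*/dn) is unchanged.
// The closure root md*(H, nD, nE) is continued in time: each cell keeps
// the membrane density of its current steady-state branch and a damped
// Newton iteration warm-started from it tracks that branch as the totals
// drift (deliberate hysteresis across saddle-node folds). The branch
// decision is frozen across the stages of a step. When the tracked branch
// disappears (fold), the cell re-scans all branches and adopts the one
// whose contact values are nearest its relaxed cytosol state.
#include <RcppArmadillo.h>
using namespace Rcpp;

namespace {

struct MPars {
  double kD, kdD, kdE, kde;
};

inline double gap(double md, double H, double nD, double nE, double gamH,
                  const MPars& P) {
  double mde = P.kdE * md * nE / (P.kde + P.kdE * md / H);
  double cE0 = nE - mde / H;
  double cD0 = nD - (md + mde) / H;
  return (P.kD + P.kdD * md) * (cD0 - P.kde * mde / gamH) -
         P.kdE * md * cE0;
}

inline void from_md(double md, double H, double nD, double nE, double gamH,
                    const MPars& P, double& cD0, double& cDD0, double& cE0) {
  double mde = P.kdE * md * nE / (P.kde + P.kdE * md / H);
  cE0 = nE - mde / H;
  cD0 = nD - (md + mde) / H;
  cDD0 = P.kde * mde / gamH;
}

inline double md_cap(double H, double nD, double nE, const MPars& P) {
  double a = P.kdE / H;
  double b = P.kde + P.kdE * nE - P.kdE * nD;
  double c = -nD * H * P.kde;
  return (-b + std::sqrt(b * b - 4.0 * a * c)) / (2.0 * a);
}

// track the branch through a damped Newton from md0; returns -1 on failure
inline double track_branch(double md0, double H, double nD, double nE,
                           double gamH, const MPars& P, double gscale) {
  double cap = md_cap(H, nD, nE, P);
  double m = md0 < cap ? (md0 > 0.0 ? md0 : 0.0) : cap;
  for (int it = 0; it < 40; ++it) {
    double g = gap(m, H, nD, nE, gamH, P);
    double h = 1e-7 * (1.0 + m);
    double gp = (gap(m + h, H, nD, nE, gamH, P) -
                 gap(m - h, H, nD, nE, gamH, P)) / (2.0 * h);
    if (gp == 0.0 || !std::isfinite(gp)) return -1.0;
    double step = g / gp;
    double lim = 0.2 * (1.0 + m);
    if (step > lim) step = lim; else if (step < -lim) step = -lim;
    m -= step;
    if (m < 0.0) m = 0.0;
    if (m > cap) m = cap;
    if (std::fabs(step) < 1e-12 * (1.0 + m)) {
      if (std::fabs(gap(m, H, nD, nE, gamH, P)) < 1e-8 * gscale) {
        double cD0, cDD0, cE0;
        from_md(m, H, nD, nE, gamH, P, cD0, cDD0, cE0);
        if (cD0 >= -1e-9 && cE0 >= -1e-9 && cD0 - cDD0 >= -1e-6 * (1.0 + nD))
          return m;
      }
      return -1.0;
    }
  }
  return -1.0;
}

// full multi-branch scan; selects branch nearest (auxD, auxE) in contact
// space; returns md of the selected branch
inline double rescan(double H, double nD, double nE, double gamH,
                     const MPars& P, double auxD, double auxE, int n_scan) {
  double cap = md_cap(H, nD, nE, P);
  double best = 1e300, md_sel = cap;
  double gprev = gap(0.0, H, nD, nE, gamH, P);
  double fprev = 0.0;
  bool found = false;
  for (int k = 1; k < n_scan; ++k) {
    double f = double(k) / double(n_scan - 1);
    f = f * f;
    double md = cap * f;
    double g = gap(md, H, nD, nE, gamH, P);
    if (gprev == 0.0 || gprev * g < 0.0) {
      double lo = cap * fprev, hi = md, glo = gprev;
      for (int it = 0; it < 50; ++it) {
        double mid = 0.5 * (lo + hi);
        double gm = gap(mid, H, nD, nE, gamH, P);
        if (glo * gm > 0.0) { lo = mid; glo = gm; } else hi = mid;
      }
      double root = 0.5 * (lo + hi);
      double cd, cdd, ce;
      from_md(root, H, nD, nE, gamH, P, cd, cdd, ce);
      double d2 = (cd - auxD) * (cd - auxD) + (ce - auxE) * (ce - auxE);
      if (!found || d2 < best) { best = d2; md_sel = root; found = true; }
    }
    gprev = g; fprev = f;
  }
  return md_sel;
}

struct Model {
  int n;
  arma::vec Hc, Hf, gamH;
  double dx, Dc, kappa, gscale;
  MPars P;
  int n_scan;
  arma::vec md_branch;   // tracked branch per cell (frozen within a step)
  arma::vec cDs, cEs;    // closure values at the frozen branch state

  // refresh the closure (and branch memory) from the current state
  void update_closure(const arma::vec& y) {
    const double* nD = y.memptr();
    const double* nE = y.memptr() + n;
    const double* cD = y.memptr() + 2 * n;
    const double* cE = y.memptr() + 3 * n;
    for (int i = 0; i < n; ++i) {
      double nDi = nD[i] > 0.0 ? nD[i] : 0.0;
      double nEi = nE[i] > 0.0 ? nE[i] : 0.0;
      if (nDi <= 0.0) { md_branch(i) = 0.0; cDs(i) = 0.0; cEs(i) = nEi; continue; }
      if (nEi <= 0.0) { md_branch(i) = nDi * Hc(i); cDs(i) = 0.0; cEs(i) = 0.0; continue; }
      double m = track_branch(md_branch(i), Hc(i), nDi, nEi, gamH(i), P,
                              gscale);
      if (m < 0.0) {
        m = rescan(Hc(i), nDi, nEi, gamH(i), P, cD[i], cE[i], n_scan);
      }
      md_branch(i) = m;
      double cd, cdd, ce;
      from_md(m, Hc(i), nDi, nEi, gamH(i), P, cd, cdd, ce);
      cDs(i) = cd; cEs(i) = ce;
    }
  }

  // rhs with the closure frozen at (cDs, cEs) for the branch decision;
  // within a stage the closure values are re-tracked from the frozen
  // branch to stay consistent with the stage state
  void rhs(const arma::vec& y, arma::vec& dy) const {
    const double* nD = y.memptr();
    const double* nE = y.memptr() + n;
    const double* cD = y.memptr() + 2 * n;
    const double* cE = y.memptr() + 3 * n;
    double* dnD = dy.memptr();
    double* dnE = dy.memptr() + n;
    double* dcD = dy.memptr() + 2 * n;
    double* dcE = dy.memptr() + 3 * n;
    double fDl = 0.0, fEl = 0.0;
    for (int i = 0; i < n; ++i) {
      double fDr = 0.0, fEr = 0.0;
      if (i + 1 < n) {
        fDr = Hf(i) * Dc * (cD[i + 1] - cD[i]) / dx;
        fEr = Hf(i) * Dc * (cE[i + 1] - cE[i]) / dx;
      }
      dnD[i] = (fDr - fDl) / (dx * Hc(i));
      dnE[i] = (fEr - fEl) / (dx * Hc(i));
      fDl = fDr; fEl = fEr;
    }
    for (int i = 0; i < n; ++i) {
      double nDi = nD[i] > 0.0 ? nD[i] : 0.0;
      double nEi = nE[i] > 0.0 ? nE[i] : 0.0;
      double cs = cDs(i), es = cEs(i);
      if (nDi <= 0.0) { cs = 0.0; es = nEi; }
      else if (nEi <= 0.0) { cs = 0.0; es = 0.0; }
      else {
        double m = track_branch(md_branch(i), Hc(i), nDi, nEi, gamH(i), P,
                                gscale);
        if (m >= 0.0) {
          double cd, cdd, ce;
          from_md(m, Hc(i), nDi, nEi, gamH(i), P, cd, cdd, ce);
          cs = cd; es = ce;
        }
        // if the branch vanished mid-stage, keep the frozen closure values
      }
      // diffusion of the auxiliary field uses the same flux-form operator
      // already evaluated for the totals
      dcD[i] = kappa * (cs - cD[i]) + dnD[i];
      dcE[i] = kappa * (es - cE[i]) + dnE[i];
    }
  }
};

}  // namespace

// [[Rcpp::export]]
List reduced_integrate_cpp(arma::vec nD, arma::vec nE,
                           arma::vec cD, arma::vec cE,
                           arma::vec Hc, arma::vec Hf, double dx,
                           List pars, double kappa, double dt,
                           arma::vec t_out, int n_scan) {
  Model mod;
  mod.n = nD.n_elem;
  mod.Hc = Hc; mod.Hf = Hf; mod.dx = dx;
  mod.Dc = pars["Dc"]; mod.kappa = kappa;
  mod.P.kD = pars["kD"]; mod.P.kdD = pars["kdD"];
  mod.P.kdE = pars["kdE"]; mod.P.kde = pars["kde"];
  double lam = pars["lam"];
  mod.gamH = std::sqrt(mod.Dc * lam) *
             arma::tanh(std::sqrt(lam / mod.Dc) * Hc);
  mod.n_scan = n_scan;
  mod.gscale = mod.P.kde * (1.0 + arma::max(nE));
  mod.md_branch.zeros(mod.n);
  mod.cDs.zeros(mod.n);
  mod.cEs.zeros(mod.n);

  int n = mod.n, nv = 4 * n;
  arma::vec y(nv);
  y.subvec(0, n - 1) = nD;
  y.subvec(n, 2 * n - 1) = nE;
  y.subvec(2 * n, 3 * n - 1) = cD;
  y.subvec(3 * n, 4 * n - 1) = cE;

  // initialize branch memory from the relaxed cytosol state
  for (int i = 0; i < n; ++i) {
    mod.md_branch(i) = rescan(Hc(i), nD(i) > 0 ? nD(i) : 0.0,
                              nE(i) > 0 ? nE(i) : 0.0, mod.gamH(i), mod.P,
                              cD(i), cE(i), n_scan);
  }
  mod.update_closure(y);

  int nout = t_out.n_elem;
  arma::mat out(nv, nout);
  arma::vec k1(nv), k2(nv), k3(nv), tmp(nv);
  double t = 0.0;
  int iout = 0;
  if (t_out(0) <= 0.0) { out.col(0) = y; iout = 1; }
  int check = 0;
  while (iout < nout) {
    double h = dt;
    if (t + h > t_out(iout)) h = t_out(iout) - t;
    // SSPRK3 in increment form with the branch decision frozen over the
    // step: adding one small increment to the state per step keeps the
    // round-off drift of the conserved totals a random walk instead of
    // the biased drift that repeated convex recombinations of the state
    // would give
    mod.rhs(y, k1);
    tmp = y + h * k1;
    mod.rhs(tmp, k2);
    tmp = y + 0.25 * h * (k1 + k2);
    mod.rhs(tmp, k3);
    y += (h / 6.0) * (k1 + k2 + 4.0 * k3);
    t += h;
    mod.update_closure(y);
    if (t >= t_out(iout) - 1e-9 * (1.0 + t_out(iout))) {
      out.col(iout) = y;
      ++iout;
    }
    if (++check == 200) {
      check = 0;
      if (!y.is_finite()) {
        stop("reduced dynamics produced non-finite values at t = %f", t);
      }
      Rcpp::checkUserInterrupt();
    }
  }
  return List::create(_["t"] = t_out, _["y"] = out);
}
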