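// 2D (y,z) nonlinear simulator of the Min skeleton model in a slice:
// bulk diffusion of (cD, cDD, cE) with nucleotide exchange on cDD,
// membrane line at z = 0 carrying (md, mde) with slow diffusion and
// mass-action kinetics, coupled through reactive boundary fluxes.
//
// Scheme (per step, first order in dt, direction-split):
//   1. coupled implicit column step: backward-Euler z-diffusion of each
//      bulk column TOGETHER with the interface kinetics. Writing the
//      bulk update as c_new = T^{-1} c_old + g * f, where T is the
//      backward-Euler flux-form tridiagonal, g = T^{-1} (dt/h1) e1 the
//      response of the column to a unit boundary flux, and f the reactive
//      flux, gives a closed 5-variable nonlinear system per column in
//      (md, mde, cD1, cDD1, cE1), solved by Newton with the analytic
//      Jacobian. Splitting the interface kinetics from vertical diffusion
//      instead would be inaccurate: the thin bottom cell exchanges with
//      its neighbour on a timescale h1^2/Dc far below dt.
//   2. implicit y-diffusion of the bulk fields and the membrane fields
//      (backward Euler, Thomas / cyclic Thomas).
// Column mass bookkeeping is exact for any Newton iterate because the
// same rate evaluations define the membrane update and the boundary flux
// into the column (flux-form T preserves the h-weighted column sum).
#include <RcppArmadillo.h>
using namespace Rcpp;

namespace {

struct Tri {
  arma::vec low, diag, up;   // original coefficients
  arma::vec cp;              // modified upper diagonal
  void factor() {
    int n = diag.n_elem;
    cp.set_size(n);
    cp(0) = up(0) / diag(0);
    for (int i = 1; i < n; ++i)
      cp(i) = up(i) / (diag(i) - low(i) * cp(i - 1));
  }
  void solve(double* d) const {
    int n = diag.n_elem;
    d[0] /= diag(0);
    for (int i = 1; i < n; ++i)
      d[i] = (d[i] - low(i) * d[i - 1]) / (diag(i) - low(i) * cp(i - 1));
    for (int i = n - 2; i >= 0; --i)
      d[i] -= cp(i) * d[i + 1];
  }
};

// backward-Euler matrix (I - dt*(flux-form Laplacian) + dt*decay)
Tri be_matrix(const arma::vec& h, const arma::vec& zc, double D, double dt,
              double decay) {
  int n = h.n_elem;
  Tri T;
  T.low.zeros(n); T.diag.zeros(n); T.up.zeros(n);
  for (int i = 0; i < n; ++i) T.diag(i) = 1.0 + dt * decay;
  for (int i = 0; i + 1 < n; ++i) {
    double w = D / (zc(i + 1) - zc(i));
    T.diag(i)     += dt * w / h(i);
    T.up(i)       -= dt * w / h(i);
    T.diag(i + 1) += dt * w / h(i + 1);
    T.low(i + 1)  -= dt * w / h(i + 1);
  }
  T.factor();
  return T;
}

// cyclic (periodic) tridiagonal via Sherman-Morrison
struct CyclicTri {
  Tri inner;
  arma::vec w_corr;
  double v_end;
  bool periodic;
  void build(int n, double w, double dt, double h, double decay,
             bool periodic_) {
    periodic = periodic_ && n > 2;
    inner.low.zeros(n); inner.diag.zeros(n); inner.up.zeros(n);
    for (int i = 0; i < n; ++i) inner.diag(i) = 1.0 + dt * decay;
    double a = dt * w / h;
    for (int i = 0; i + 1 < n; ++i) {
      inner.diag(i)     += a;
      inner.up(i)       -= a;
      inner.diag(i + 1) += a;
      inner.low(i + 1)  -= a;
    }
    if (periodic) {
      inner.diag(0) += a;
      inner.diag(n - 1) += a;
      double beta = -a;
      double d0 = inner.diag(0);
      double gamma = -d0;
      inner.diag(0)     -= gamma;
      inner.diag(n - 1) -= beta * beta / gamma;
      v_end = beta / gamma;
      inner.factor();
      arma::vec u(n, arma::fill::zeros);
      u(0) = gamma; u(n - 1) = beta;
      inner.solve(u.memptr());
      w_corr = u;
    } else {
      inner.factor();
    }
  }
  void solve(double* d, int n) const {
    inner.solve(d);
    if (periodic) {
      double fac = (d[0] + v_end * d[n - 1]) /
                   (1.0 + w_corr(0) + v_end * w_corr(n - 1));
      for (int i = 0; i < n; ++i) d[i] -= fac * w_corr(i);
    }
  }
};

struct Pars {
  double Dc, Dm, lam, kD, kdD, kdE, kde;
};

// Newton solve of the coupled interface/column system for one column.
// Unknowns u = (md, mde, cD1, cDD1, cE1); residuals
//   R_m  = m - m0 - dt r(u)
//   R_c  = c1 - cp1 - g1 * f(u)
// where cp1 are the boundary-flux-free implicit-diffusion predictions of
// the bottom-cell values and g1 the bottom-cell unit-flux responses.
// The kinetics act on the CONTACT concentrations c(z=0), extrapolated
// from the bottom-cell averages with the flux boundary condition
// (c0 = c1 + (zc1/Dc) f); substituting f eliminates the contact values in
// closed form and appears below as exchange-resistance denominators
// (1 + rate_coefficient * beta), beta = zc1 / Dc. Without this correction
// the effective attachment rates carry an O(zc1) bias.
inline bool interface_newton(const Pars& P, double dt, double beta,
                             double md0, double mde0,
                             double cpD1, double cpDD1, double cpE1,
                             double gD1, double gDD1, double gE1,
                             double& md, double& mde,
                             double& cD1, double& cDD1, double& cE1) {
  double u[5] = {md, mde, cD1, cDD1, cE1};
  for (int it = 0; it < 25; ++it) {
    double cDT = u[2] - u[3];
    double pos = cDT > 0 ? cDT : 0;
    double aD = P.kD + P.kdD * u[0];
    double qD = 1.0 + aD * beta;
    double rDon = aD * pos / qD;
    double aE = P.kdE * u[0];
    double qE = 1.0 + aE * beta;
    double rDEoff = P.kde * u[1];
    double rEon = aE * (u[4] + beta * rDEoff) / qE;
    double R[5] = {
      u[0] - md0 - dt * (rDon - rEon),
      u[1] - mde0 - dt * (rEon - rDEoff),
      u[2] - cpD1 - gD1 * (rDEoff - rDon),
      u[3] - cpDD1 - gDD1 * rDEoff,
      u[4] - cpE1 - gE1 * (rDEoff - rEon)};
    // rate derivatives wrt u
    double dDon[5] = {P.kdD * pos / (qD * qD), 0,
                      (cDT > 0 ? aD / qD : 0), (cDT > 0 ? -aD / qD : 0), 0};
    double dEon[5] = {P.kdE * (u[4] + beta * rDEoff) / (qE * qE),
                      aE * beta * P.kde / qE, 0, 0, aE / qE};
    double dOff[5] = {0, P.kde, 0, 0, 0};
    double A[5][6];
    for (int c = 0; c < 5; ++c) {
      A[0][c] = (c == 0) - dt * (dDon[c] - dEon[c]);
      A[1][c] = (c == 1) - dt * (dEon[c] - dOff[c]);
      A[2][c] = (c == 2) - gD1 * (dOff[c] - dDon[c]);
      A[3][c] = (c == 3) - gDD1 * dOff[c];
      A[4][c] = (c == 4) - gE1 * (dOff[c] - dEon[c]);
    }
    for (int r = 0; r < 5; ++r) A[r][5] = -R[r];
    for (int k = 0; k < 4; ++k) {
      int piv = k;
      for (int r = k + 1; r < 5; ++r)
        if (std::fabs(A[r][k]) > std::fabs(A[piv][k])) piv = r;
      if (piv != k) for (int c = k; c < 6; ++c) std::swap(A[k][c], A[piv][c]);
      for (int r = k + 1; r < 5; ++r) {
        double f = A[r][k] / A[k][k];
        for (int c = k; c < 6; ++c) A[r][c] -= f * A[k][c];
      }
    }
    double d[5];
    for (int r = 4; r >= 0; --r) {
      double s = A[r][5];
      for (int c = r + 1; c < 5; ++c) s -= A[r][c] * d[c];
      d[r] = s / A[r][r];
    }
    double sc = 0;
    for (int i = 0; i < 5; ++i) {
      u[i] += d[i];
      double rel = std::fabs(d[i]) / (1.0 + std::fabs(u[i]));
      if (rel > sc) sc = rel;
    }
    if (sc < 1e-13) break;
    if (it == 24) return false;
  }
  md = u[0] > 0 ? u[0] : 0;
  mde = u[1] > 0 ? u[1] : 0;
  cD1 = u[2]; cDD1 = u[3]; cE1 = u[4];
  return true;
}

}  // namespace

// [[Rcpp::export]]
List slice_sim_cpp(arma::mat cD, arma::mat cDD, arma::mat cE,
                   arma::vec md, arma::vec mde,
                   arma::vec hz, arma::vec zc, double dy,
                   List pars, double dt, int nsteps, int sample_every,
                   bool periodic_y) {
  Pars P;
  P.Dc = pars["Dc"]; P.Dm = pars["Dm"]; P.lam = pars["lam"];
  P.kD = pars["kD"]; P.kdD = pars["kdD"]; P.kdE = pars["kdE"];
  P.kde = pars["kde"];
  const int Nz = cD.n_rows, Ny = cD.n_cols;
  const double h1 = hz(0);

  // implicit z systems and their unit-boundary-flux responses
  Tri TzD  = be_matrix(hz, zc, P.Dc, dt, 0.0);
  Tri TzDD = be_matrix(hz, zc, P.Dc, dt, P.lam);
  arma::vec gD(Nz, arma::fill::zeros), gDD(Nz, arma::fill::zeros);
  gD(0) = dt / h1; gDD(0) = dt / h1;
  TzD.solve(gD.memptr());
  TzDD.solve(gDD.memptr());
  // implicit y systems
  CyclicTri TyC, TyM;
  TyC.build(Ny, P.Dc / dy, dt, dy, 0.0, periodic_y);
  TyM.build(Ny, P.Dm / dy, dt, dy, 0.0, periodic_y);

  int nsamp = nsteps / sample_every + 1;
  arma::mat kymo(Ny, nsamp);
  arma::vec tsamp(nsamp), massD(nsamp), massE(nsamp);

  auto record = [&](int is, double t) {
    kymo.col(is) = md + mde;
    tsamp(is) = t;
    double mD = 0, mE = 0;
    for (int j = 0; j < Ny; ++j) {
      mD += (md(j) + mde(j)) * dy;
      mE += mde(j) * dy;
      for (int i = 0; i < Nz; ++i) {
        mD += cD(i, j) * hz(i) * dy;
        mE += cE(i, j) * hz(i) * dy;
      }
    }
    massD(is) = mD; massE(is) = mE;
  };
  record(0, 0.0);

  arma::vec row(Ny);
  int fails = 0;
  for (int step = 1; step <= nsteps; ++step) {
    // ---- coupled implicit z-diffusion + interface kinetics, per column
    for (int j = 0; j < Ny; ++j) {
      TzD.solve(cD.colptr(j));    // boundary-flux-free predictions
      TzDD.solve(cDD.colptr(j));
      TzD.solve(cE.colptr(j));
      double mdn = md(j), mden = mde(j);
      double c1 = cD(0, j), c2 = cDD(0, j), c3 = cE(0, j);
      bool ok = interface_newton(P, dt, zc(0) / P.Dc, md(j), mde(j),
                                 cD(0, j), cDD(0, j), cE(0, j),
                                 gD(0), gDD(0), gD(0),
                                 mdn, mden, c1, c2, c3);
      if (!ok) ++fails;
      // distribute the boundary flux response over the whole column
      double fD = (c1 - cD(0, j)) / gD(0);
      double fDD = (c2 - cDD(0, j)) / gDD(0);
      double fE = (c3 - cE(0, j)) / gD(0);
      for (int i = 0; i < Nz; ++i) {
        cD(i, j) += gD(i) * fD;
        cDD(i, j) += gDD(i) * fDD;
        cE(i, j) += gD(i) * fE;
      }
      md(j) = mdn; mde(j) = mden;
    }
    // ---- implicit y-diffusion
    for (int i = 0; i < Nz; ++i) {
      row = cD.row(i).t();  TyC.solve(row.memptr(), Ny); cD.row(i) = row.t();
      row = cDD.row(i).t(); TyC.solve(row.memptr(), Ny); cDD.row(i) = row.t();
      row = cE.row(i).t();  TyC.solve(row.memptr(), Ny); cE.row(i) = row.t();
    }
    row = md;  TyM.solve(row.memptr(), Ny); md = row;
    row = mde; TyM.solve(row.memptr(), Ny); mde = row;

    if (step % sample_every == 0) record(step / sample_every, step * dt);
  }
  if (fails > 0) {
    warning("interface Newton failed to converge in %d column updates",
            fails);
  }

  return List::create(
    _["kymo"] = kymo, _["t"] = tsamp,
    _["massD"] = massD, _["massE"] = massE,
    _["cD"] = cD, _["cDD"] = cDD, _["cE"] = cE,
    _["md"] = md, _["mde"] = mde);
}
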