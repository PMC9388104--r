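# Shared fixtures and independent oracles used across the suite.

p_canon <- default_min_params()

# Independent two-point BVP oracle for the stationary MinD-ADP column:
# solve Dc c'' = lam c with c'(H) = 0 by high-accuracy ODE integration
# from the top down (c(H) = 1, c'(H) = 0) and return the flux coefficient
# phi / c(0) = -Dc c'(0) / c(0). Never uses the tanh closed form.
gamma_bvp <- function(H, p) {
  rhs <- function(z, y, parms) list(c(y[2], (p$lam / p$Dc) * y[1]))
  sol <- deSolve::lsoda(c(1, 0), c(0, H), rhs, parms = NULL,
                        rtol = 1e-12, atol = 1e-12)
  cz <- sol[2, 2]; dz <- sol[2, 3]
  # integrated in s = H - z from the top down, so dc/ds(H) = -dc/dz(0)
  unname(p$Dc * dz / cz)
}

# central finite-difference Jacobians of the interface reactions/fluxes
fd_interface_jacobians <- function(cD0, cDD0, cE0, md, mde, p, h = 1e-6) {
  st <- c(md = md, mde = mde, cD0 = cD0, cDD0 = cDD0, cE0 = cE0)
  eval_rf <- function(s) {
    r <- reaction_rates(cDT = s[["cD0"]] - s[["cDD0"]], cE = s[["cE0"]],
                        md = s[["md"]], mde = s[["mde"]], p = p)
    c(r1 = r$rDon - r$rEon, r2 = r$rEon - r$rDEoff,
      f1 = r$rDEoff - r$rDon, f2 = r$rDEoff, f3 = r$rDEoff - r$rEon)
  }
  J <- sapply(names(st), function(v) {
    a <- st; b <- st
    a[[v]] <- a[[v]] + h; b[[v]] <- b[[v]] - h
    (eval_rf(a) - eval_rf(b)) / (2 * h)
  })
  list(Jr_m = J[1:2, 1:2], Jr_c = J[1:2, 3:5],
       Jf_m = J[3:5, 1:2], Jf_c = J[3:5, 3:5])
}

# independent steady-state oracle: membrane balance closed by the
# BVP-integrated bulk flux coefficient (no tanh), root in md by uniroot
hss_oracle <- function(H, nD, nE, p, md_bracket) {
  gam <- gamma_bvp(H, p)
  state_of <- function(md) {
    mde <- p$kdE * md * nE / (p$kde + p$kdE * md / H)
    cE0 <- nE - mde / H
    cD0 <- nD - (md + mde) / H
    cDD0 <- p$kde * mde / gam
    list(md = md, mde = mde, cD0 = cD0, cDD0 = cDD0, cE0 = cE0)
  }
  g <- function(md) {
    s <- state_of(md)
    (p$kD + p$kdD * md) * (s$cD0 - s$cDD0) - p$kdE * md * s$cE0
  }
  md <- stats::uniroot(g, md_bracket, tol = .Machine$double.eps)$root
  state_of(md)
}

# first positive root of the admissibility bound for bracket construction
md_cap_of <- function(H, nD, nE, p) {
  a <- p$kdE / H
  b <- p$kde + p$kdE * nE - p$kdE * nD
  cc <- -nD * H * p$kde
  (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
}
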