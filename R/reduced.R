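#' Local-equilibria closure of the slice-averaged cytosol concentrations
#'
#' Approximates the slice-averaged cytosol concentrations by the
#' homogeneous-steady-state contact values of each slice,
#' `c_i(x) ~ c_i*(H(x), nD(x), nE(x))` (at an HSS the stationary cD and cE
#' are z-uniform, so contact and z-average coincide). Where slices are
#' multistable the branch is selected by continuation: a damped Newton
#' iteration on the scalar steady-state condition is warm-started from the
#' previous map, which deliberately makes the closure hysteretic across
#' saddle-node folds. Cells where the warm start fails (typically because
#' the previous branch just folded) are re-solved from scratch and the
#' branch nearest the supplied relaxed cytosol values is taken.
#'
#' @param nD,nE Numeric profiles of slice totals \[1/um^3\].
#' @param H Numeric profile of slice heights \[um\] (same length).
#' @param p A [min_params()] object.
#' @param previous Optional previous closure map (as returned by this
#'   function); used as the Newton warm start.
#' @param aux Optional list with `cD`, `cE`: relaxed cytosol profiles used
#'   to pick a branch where a fresh solve is needed.
#' @return A tibble of class `closure_map` with columns `H`, `nD`, `nE`,
#'   `md`, `mde`, `cD_star`, `cDD_star`, `cE_star`, `refreshed` (logical:
#'   cell needed a fresh multi-branch solve).
#' @export
closure <- function(nD, nE, H, p, previous = NULL, aux = NULL) {
  cc <- closure_core(nD, nE, H, p,
                     md_prev = if (!is.null(previous)) previous$md else NULL,
                     aux = aux)
  structure(tibble::tibble(H = H, nD = nD, nE = nE, md = cc$md,
                           mde = cc$mde, cD_star = cc$cD, cDD_star = cc$cDD,
                           cE_star = cc$cE, refreshed = cc$refreshed),
            class = c("closure_map", class(tibble::tibble())))
}

# Largest admissible membrane MinD density (cD0 = 0): closed-form positive
# root of the quadratic md + mde(md) = nD * H.
md_upper <- function(H, nD, nE, p) {
  a <- p$kdE / H
  b <- p$kde + p$kdE * nE - p$kdE * nD
  cc <- -nD * H * p$kde
  (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
}

# hot-path closure: plain vectors in, plain list out. Deterministic in the
# state: all steady-state branches of every cell are located by a fixed
# bracket scan + bisection (vectorized across cells and brackets), then one
# branch per cell is selected -- nearest in md to `md_prev` if given,
# else nearest in (cD*, cE*) to `aux`, else the branch with smallest cD*.
closure_core <- function(nD, nE, H, p, md_prev = NULL, aux = NULL,
                         n_scan = 64L) {
  n <- length(nD)
  out <- list(md = numeric(n), mde = numeric(n), cD = numeric(n),
              cDD = numeric(n), cE = numeric(n), refreshed = rep(FALSE, n))
  live <- which(nD > 0 & nE > 0)
  # analytic corners
  zD <- which(nD == 0)
  if (length(zD)) out$cE[zD] <- nE[zD]
  zE <- which(nE == 0 & nD > 0)
  if (length(zE)) out$md[zE] <- nD[zE] * H[zE]
  if (!length(live)) return(out)

  Hl <- H[live]; nDl <- nD[live]; nEl <- nE[live]
  nl <- length(live)
  cap <- md_upper(Hl, nDl, nEl, p)
  gamH <- sqrt(p$Dc * p$lam) * tanh(sqrt(p$lam / p$Dc) * Hl)
  kD <- p$kD; kdD <- p$kdD; kdE <- p$kdE; kde <- p$kde
  # inlined stationarity gap (vector md, recycled per-cell constants)
  gap <- function(md, Hv, nDv, nEv, gv) {
    mde <- kdE * md * nEv / (kde + kdE * md / Hv)
    cE0 <- nEv - mde / Hv
    cD0 <- nDv - (md + mde) / Hv
    (kD + kdD * md) * (cD0 - kde * mde / gv) - kdE * md * cE0
  }
  frac <- seq(0, 1, length.out = n_scan)^2
  # g > 0 at md = 0 and g < 0 at md = cap: odd root count, >= 1 bracket
  G <- matrix(gap(rep(cap, n_scan) * rep(frac, each = nl),
                  rep(Hl, n_scan), rep(nDl, n_scan), rep(nEl, n_scan),
                  rep(gamH, n_scan)),
              nl, n_scan)
  flips <- G[, -1, drop = FALSE] * G[, -n_scan, drop = FALSE] < 0
  chg <- which(flips, arr.ind = TRUE)
  cell <- chg[, 1]; lo <- chg[, 2]
  miss <- setdiff(seq_len(nl), unique(cell))   # degenerate: no sign change
  if (length(miss)) {
    cell <- c(cell, miss); lo <- c(lo, rep(n_scan - 1L, length(miss)))
  }
  a <- cap[cell] * frac[lo]; b <- cap[cell] * frac[lo + 1L]
  ga <- G[cbind(cell, lo)]
  Hb <- Hl[cell]; nDb <- nDl[cell]; nEb <- nEl[cell]; gb <- gamH[cell]
  for (it in 1:48) {
    m <- (a + b) / 2
    gm <- gap(m, Hb, nDb, nEb, gb)
    left <- ga * gm > 0
    a[left] <- m[left]; ga[left] <- gm[left]
    b[!left] <- m[!left]
  }
  root <- (a + b) / 2
  s <- hss_from_md(root, Hb, nDb, nEb, p)

  # branch selection per cell
  if (!is.null(md_prev)) {
    dist <- abs(root - md_prev[live][cell])
  } else if (!is.null(aux)) {
    dist <- sqrt((s$cD0 - aux$cD[live][cell])^2 +
                   (s$cE0 - aux$cE[live][cell])^2)
  } else {
    dist <- s$cD0
  }
  ord <- order(cell, dist)
  pick <- ord[!duplicated(cell[ord])]
  sel_cell <- live[cell[pick]]
  out$md[sel_cell] <- s$md[pick]
  out$mde[sel_cell] <- s$mde[pick]
  out$cD[sel_cell] <- s$cD0[pick]
  out$cDD[sel_cell] <- s$cDD0[pick]
  out$cE[sel_cell] <- s$cE0[pick]
  out
}

# finite-volume divergence of the height-weighted diffusive flux:
# (1/H_i) * d/dx [ H Dc dC/dx ] with no-flux ends; exact discrete
# conservation of sum(H_i C-source) by telescoping.
fv_div <- function(cvec, Hc, Hf, Dc, dx) {
  n <- length(cvec)
  flux <- Hf * Dc * diff(cvec) / dx         # at interior faces, n-1 values
  div <- (c(flux, 0) - c(0, flux)) / dx
  div / Hc
}

#' Right-hand side of the reduced wedge dynamics
#'
#' The closed large-scale dynamics for the slice totals on the wedge axis:
#' `dt n_i = (1/H) dx( H Dc dx c_i_aux )` in conservative flux form
#' (equivalent to the two-term form `Dc dxx c + Dc (dx H / H) dx c` for
#' smooth fields), with the relaxed cytosol variables
#' `dt c_i_aux = kappa (c_i* - c_i_aux) + (1/H) dx( H Dc dx c_i_aux )`
#' slaved to the local-equilibria closure on a fast timescale while also
#' diffusing. The diffusion term in the auxiliary dynamics is essential
#' for well-posedness: in laterally unstable regions the closure slope
#' matrix `dc*/dn` has a negative eigenvalue (the physical mass-
#' redistribution instability), and pointwise relaxation alone would let
#' perturbations grow at a rate `sqrt(kappa Dc |S|) q`, unbounded in the
#' wavenumber; with cytosol diffusion the growth saturates at `kappa |S|`
#' and the large-scale effective-diffusion limit is unchanged. Membrane
#' diffusion is neglected (it is two orders of magnitude slower than bulk
#' diffusion). No-flux boundaries at both ends make the wedge a closed
#' system; the cell-centred flux form conserves both totals
#' `sum_i H_i n_i dx` to round-off.
#'
#' @param state List with numeric profiles `nD`, `nE`, `cD_aux`, `cE_aux`
#'   on the cell centers.
#' @param geometry A [wedge_geometry()].
#' @param p A [min_params()] object.
#' @param kappa Relaxation rate of the auxiliary cytosol variables \[1/s\].
#' @param x Cell-center positions (defaults to a uniform grid over
#'   `[0, L]` from the profile length).
#' @return List with `dnD`, `dnE`, `dcD_aux`, `dcE_aux` and the `closure`
#'   map used.
#' @export
reduced_rhs <- function(state, geometry, p, kappa = 1, x = NULL) {
  if (kappa <= 0) stop("relaxation rate kappa must be positive")
  n <- length(state$nD)
  if (is.null(x)) {
    dx <- geometry$L / n
    x <- (seq_len(n) - 0.5) * dx
  } else dx <- x[2] - x[1]
  Hc <- geometry$H(x)
  Hf <- geometry$H((x[-n] + x[-1]) / 2)
  # branch selection through the relaxed variables keeps the right-hand
  # side a pure function of the state (hysteresis is carried by c_aux)
  cm <- closure_core(state$nD, state$nE, Hc, p,
                     aux = list(cD = state$cD_aux, cE = state$cE_aux))
  divD <- fv_div(state$cD_aux, Hc, Hf, p$Dc, dx)
  divE <- fv_div(state$cE_aux, Hc, Hf, p$Dc, dx)
  list(
    dnD = divD,
    dnE = divE,
    dcD_aux = kappa * (cm$cD - state$cD_aux) + divD,
    dcE_aux = kappa * (cm$cE - state$cE_aux) + divE,
    closure = cm
  )
}

#' Initial reduced state: uniform totals on the wedge
#'
#' The canonical initial condition: both slice totals uniform at the global
#' averages (proteins uniformly distributed in the bulk), with the
#' auxiliary cytosol variables initialized on the steady-state branch
#' continuous along the wedge axis (via [hss_continuation()] in x).
#'
#' @param geometry A [wedge_geometry()].
#' @param p A [min_params()] object.
#' @param n_cells Number of finite-volume cells.
#' @return A list with `x`, `nD`, `nE`, `cD_aux`, `cE_aux`.
#' @export
reduced_state_init <- function(geometry, p, n_cells = 200) {
  dx <- geometry$L / n_cells
  x <- (seq_len(n_cells) - 0.5) * dx
  path <- tibble::tibble(H = geometry$H(x), nD = p$nD_bar, nE = p$nE_bar)
  cont <- hss_continuation(path, p)
  cD <- vapply(cont$sets, function(s) s$cD0[1], numeric(1))
  cE <- vapply(cont$sets, function(s) s$cE0[1], numeric(1))
  list(x = x, nD = rep(p$nD_bar, n_cells), nE = rep(p$nE_bar, n_cells),
       cD_aux = cD, cE_aux = cE)
}

#' Integrate the reduced wedge dynamics
#'
#' Advances the closed slice-total dynamics with a strong-stability-
#' preserving third-order Runge-Kutta scheme at a fixed step (compiled
#' core). Runge-Kutta steps preserve linear invariants exactly, so the two
#' wedge masses are conserved to round-off; the realized drift is recorded
#' on the trajectory. In regions where the local slices are laterally
#' unstable the closure makes the mass dynamics locally anti-diffusive --
#' the physical mechanism that seeds patterns there -- and the relaxation
#' regularization keeps the resulting growth bounded at the grid scale; a
#' fixed step marches robustly through this regime where error-controlled
#' steppers stall on the (physically meaningless) fine structure.
#'
#' The default step of 0.02 s respects the explicit diffusion limit of the
#' auxiliary cytosol field on the default 200-cell grid
#' (`dt < 2.5 dx^2 / (4 Dc)` for the third-order scheme) with margin;
#' halving it changes smooth-region profiles at the 1e-6 level.
#'
#' @param state0 Initial state from [reduced_state_init()] (or compatible
#'   list with `x`, `nD`, `nE`, `cD_aux`, `cE_aux`).
#' @param geometry A [wedge_geometry()].
#' @param p A [min_params()] object.
#' @param T Final time \[s\].
#' @param n_out Number of output snapshots (including t = 0).
#' @param kappa Relaxation rate \[1/s\] of the auxiliary variables.
#' @param dt Time step \[s\].
#' @return A tibble of class `reduced_trajectory`, long format with columns
#'   `t`, `x`, `H`, `nD`, `nE`, `cD_aux`, `cE_aux`; attributes `geometry`,
#'   `kappa`, `mass_error` (max relative drift of the two wedge masses).
#' @export
integrate_reduced <- function(state0, geometry, p, T, n_out = 41, kappa = 1,
                              dt = 0.02) {
  n <- length(state0$nD)
  x <- state0$x
  Hc <- geometry$H(x)
  dx <- x[2] - x[1]
  Hf <- geometry$H((x[-n] + x[-1]) / 2)
  times <- seq(0, T, length.out = n_out)
  res <- reduced_integrate_cpp(state0$nD, state0$nE,
                               state0$cD_aux, state0$cE_aux,
                               Hc, Hf, dx,
                               p[c("Dc", "kD", "kdD", "kdE", "kde", "lam")],
                               kappa, dt, times, 64L)
  snaps <- lapply(seq_along(times), function(i) {
    v <- res$y[, i]
    tibble::tibble(t = times[i], x = x, H = Hc,
                   nD = v[1:n], nE = v[n + 1:n],
                   cD_aux = v[2 * n + 1:n], cE_aux = v[3 * n + 1:n])
  })
  out <- dplyr::bind_rows(snaps)
  mass <- function(sn, col) sum(Hc * sn[[col]] * dx)
  m0D <- mass(snaps[[1]], "nD"); m0E <- mass(snaps[[1]], "nE")
  drift <- max(vapply(snaps, function(sn)
    max(abs(mass(sn, "nD") / m0D - 1), abs(mass(sn, "nE") / m0E - 1)),
    numeric(1)))
  structure(out, class = c("reduced_trajectory", class(out)),
            geometry = geometry, kappa = kappa, mass_error = drift)
}
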