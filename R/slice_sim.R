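#' Simulate the full nonlinear Min dynamics in a 2D slice
#'
#' Method-of-lines simulation of the bulk-surface Min model in a
#' rectangular slice: bulk fields (cD, cDD, cE) on a (y, z) grid with
#' nucleotide exchange acting on cDD, membrane fields (md, mde) on the
#' bottom edge, coupled by reactive boundary fluxes. Diffusion is treated
#' implicitly (direction-split backward Euler in flux form, unconditionally
#' stable), the interface kinetics explicitly (midpoint rule) inside a
#' Strang splitting; identical rate evaluations update the membrane and the
#' adjacent bulk cell, so the two conserved totals drift only at round-off
#' level. The z grid is refined towards the membrane to resolve the
#' reactive boundary layer of width `sqrt(Dc/lam)`.
#'
#' @param H Slice bulk height \[um\].
#' @param L_y Lateral slice length \[um\].
#' @param p A [min_params()] object.
#' @param T Simulated time \[s\].
#' @param nD,nE Slice total densities (defaults: the global averages in
#'   `p`).
#' @param init Either `"hss"` (start exactly on the homogeneous steady
#'   state), `"noise"` (HSS plus a small random lateral perturbation of the
#'   membrane fields), or `"cos"` (HSS plus a single-mode perturbation
#'   `eps * md * cos(q y)`).
#' @param q Wavenumber of the `"cos"` perturbation; snapped to the nearest
#'   admissible lateral mode.
#' @param eps Relative perturbation amplitude (default 1e-3 for noise,
#'   1e-4 for the single-mode start).
#' @param seed Integer seed for the `"noise"` initialization.
#' @param n_y,n_z Lateral and vertical grid resolution.
#' @param dt Time step \[s\].
#' @param sample_dt Sampling cadence of the membrane kymograph \[s\].
#' @param periodic_y Use periodic instead of no-flux lateral boundaries.
#' @param relax_T Length \[s\] of a single-column pre-relaxation run that
#'   settles the laterally uniform background onto the exact fixed point
#'   of the discrete scheme before the perturbation is applied (useful for
#'   clean growth-rate measurements; requires the column dynamics to be
#'   stable). 0 disables it.
#' @return An object of class `slice_fields`: list with `y`, `z`, `t`,
#'   `kymo` (membrane density md+mde, y x time), final bulk/membrane
#'   fields, `mass` (tibble of total MinD/MinE over time), `hss` (the
#'   branch used), `q` (actual perturbation wavenumber or NA), `seed`.
#' @export
simulate_slice <- function(H, L_y, p, T, nD = p$nD_bar, nE = p$nE_bar,
                           init = c("noise", "hss", "cos"), q = NULL,
                           eps = NULL, seed = 1L, n_y = 128, n_z = 48,
                           dt = 0.01, sample_dt = 1, periodic_y = FALSE,
                           relax_T = 0) {
  init <- match.arg(init)
  stopifnot(H > 0, L_y > 0, T > 0)
  hss <- solve_hss(H, nD, nE, p)
  hss <- hss[nrow(hss), ]   # densest-cytosol branch when multistable

  # sinh-stretched z grid refined at the membrane
  a <- 3
  zf <- H * sinh(a * seq(0, 1, length.out = n_z + 1)) / sinh(a)
  hz <- diff(zf)
  zc <- (zf[-1] + zf[-(n_z + 1)]) / 2
  dy <- L_y / n_y
  y <- (seq_len(n_y) - 0.5) * dy
  pars <- p[c("Dc", "Dm", "lam", "kD", "kdD", "kdE", "kde")]

  # steady state consistent with the DISCRETE vertical operator: solve the
  # stationary cDD column for a unit boundary flux, recompute the flux
  # coefficient gamma_H = phi / cDD(0) from it, and re-solve the scalar
  # steady-state condition with that coefficient
  col <- discrete_hss_column(hss$md, H, nD, nE, p, hz, zc)
  md0 <- col$md; mde0 <- col$mde
  cD <- matrix(col$cD0, n_z, n_y)
  cDD <- matrix(col$cDD_prof, n_z, n_y)
  cE <- matrix(col$cE0, n_z, n_y)
  md <- rep(md0, n_y)
  mde <- rep(mde0, n_y)

  if (relax_T > 0) {
    rl <- slice_sim_cpp(cD[, 1, drop = FALSE], cDD[, 1, drop = FALSE],
                        cE[, 1, drop = FALSE],
                        md[1], mde[1], hz, zc, dy, pars, dt,
                        as.integer(ceiling(relax_T / dt)),
                        as.integer(ceiling(relax_T / dt)), FALSE)
    cD <- matrix(rl$cD, n_z, n_y)
    cDD <- matrix(rl$cDD, n_z, n_y)
    cE <- matrix(rl$cE, n_z, n_y)
    md <- rep(rl$md[1], n_y)
    mde <- rep(rl$mde[1], n_y)
  }

  q_used <- NA_real_
  if (init == "noise") {
    if (is.null(eps)) eps <- 1e-3
    set.seed(seed)
    md <- md * (1 + eps * stats::runif(n_y, -1, 1))
    mde <- mde * (1 + eps * stats::runif(n_y, -1, 1))
  } else if (init == "cos") {
    if (is.null(eps)) eps <- 1e-4
    if (is.null(q)) stop("init = 'cos' requires a wavenumber q")
    k <- if (periodic_y) max(1, round(q * L_y / (2 * pi))) else
      max(1, round(q * L_y / pi))
    q_used <- if (periodic_y) 2 * pi * k / L_y else pi * k / L_y
    md <- md * (1 + eps * cos(q_used * y))
  }

  nsteps <- ceiling(T / dt)
  sample_every <- max(1L, round(sample_dt / dt))
  res <- slice_sim_cpp(cD, cDD, cE, md, mde, hz, zc, dy, pars,
                       dt, as.integer(nsteps), as.integer(sample_every),
                       periodic_y)
  mass <- tibble::tibble(t = res$t,
                         massD = res$massD / (L_y * H),
                         massE = res$massE / (L_y * H))
  structure(list(
    y = y, z = zc, t = res$t, kymo = res$kymo,
    cD = res$cD, cDD = res$cDD, cE = res$cE,
    md = res$md, mde = res$mde,
    mass = mass, hss = hss, p = p, H = H, L_y = L_y,
    q = q_used, seed = if (init == "noise") seed else NA_integer_,
    dt = dt, periodic_y = periodic_y
  ), class = "slice_fields")
}

# Steady column state consistent with the discrete vertical diffusion
# operator: gamma_H is recomputed from the discrete stationary cDD column
# under a unit boundary flux, and the scalar steady-state condition is
# re-solved with it (warm-started from the continuum membrane density).
discrete_hss_column <- function(md_cont, H, nD, nE, p, hz, zc) {
  n <- length(hz)
  if (nD <= 0 || nE <= 0 || md_cont <= 0) {
    s <- hss_from_md(max(md_cont, 0), H, nD, nE, p)
    return(list(md = s$md, mde = s$mde, cD0 = s$cD0, cE0 = s$cE0,
                cDD_prof = rep(s$cDD0, n)))
  }
  # (lam I - Dc Lz) u = e1 / h1  with flux-form Lz, no-flux ends
  M <- matrix(0, n, n)
  diag(M) <- p$lam
  for (i in seq_len(n - 1)) {
    w <- p$Dc / (zc[i + 1] - zc[i])
    M[i, i] <- M[i, i] + w / hz[i]
    M[i, i + 1] <- M[i, i + 1] - w / hz[i]
    M[i + 1, i + 1] <- M[i + 1, i + 1] + w / hz[i + 1]
    M[i + 1, i] <- M[i + 1, i] - w / hz[i + 1]
  }
  rhs <- c(1 / hz[1], rep(0, n - 1))
  u <- solve(M, rhs)
  # the kinetics act on contact values extrapolated from the bottom cell
  # with the flux boundary condition, c0 = c1 + (zc1/Dc) f, so the
  # effective discrete flux coefficient is phi / c0 = 1 / (u1 + zc1/Dc)
  gamH <- 1 / (u[1] + zc[1] / p$Dc)
  g <- function(m) hss_gap(m, H, nD, nE, p, gamH = gamH)
  lo <- md_cont / 4; hi <- md_cont * 4
  while (g(lo) * g(hi) > 0 && hi / lo < 1e6) { lo <- lo / 2; hi <- hi * 2 }
  md <- stats::uniroot(g, c(lo, hi), tol = .Machine$double.eps)$root
  s <- hss_from_md(md, H, nD, nE, p, gamH = gamH)
  phi <- p$kde * s$mde
  list(md = s$md, mde = s$mde, cD0 = s$cD0, cE0 = s$cE0,
       cDD_prof = u * phi)
}

#' @export
print.slice_fields <- function(x, ...) {
  cat(sprintf("Min slice simulation: H = %g um, L_y = %g um, t up to %g s\n",
              x$H, x$L_y, max(x$t)))
  cat(sprintf("  grid %d (y) x %d (z), membrane kymograph %d x %d\n",
              length(x$y), length(x$z), nrow(x$kymo), ncol(x$kymo)))
  invisible(x)
}

#' Membrane density kymograph of a slice run
#'
#' Extracts the total membrane-bound MinD density (md + mde) over (y, t)
#' with its metadata, the observable used for pattern classification.
#'
#' @param fields A `slice_fields` object from [simulate_slice()].
#' @return A matrix (y x t) of class `membrane_kymograph` with attributes
#'   `y`, `t`, `H`, `seed`.
#' @export
membrane_kymograph <- function(fields) {
  stopifnot(inherits(fields, "slice_fields"))
  structure(fields$kymo, class = c("membrane_kymograph", "matrix", "array"),
            y = fields$y, t = fields$t, H = fields$H, seed = fields$seed)
}

#' Fit an exponentially growing (possibly oscillatory) mode amplitude
#'
#' Least-squares fit of `b(t) = exp(r t) (c1 cos(w t) + c2 sin(w t))` to a
#' mode-amplitude time series, linear in `(c1, c2)` at fixed `(r, w)` with
#' an outer optimization over `(r, w)`. Used to measure the realized
#' linear growth rate of a seeded perturbation in [simulate_slice()] for
#' comparison with `Re sigma(q)` from the dispersion relation. The
#' frequency is seeded from the dominant discrete-Fourier peak of the
#' detrended series and the rate from the slope of `log |b|` at its local
#' maxima.
#'
#' @param t Time stamps (uniform).
#' @param b Signed mode amplitude (e.g. the cos(q y) Fourier coefficient of
#'   the membrane density perturbation).
#' @return List with `rate`, `freq`, `fitted`, `r2`.
#' @export
fit_growth_rate <- function(t, b) {
  stopifnot(length(t) == length(b), length(t) >= 8)
  dtau <- t[2] - t[1]
  # frequency seed from FFT of the detrended, demeaned series
  bb <- b - mean(b)
  sp <- Mod(stats::fft(bb))[2:(floor(length(bb) / 2))]
  f0 <- 2 * pi * which.max(sp) / (length(bb) * dtau)
  # rate seed from envelope maxima
  env <- abs(b)
  pk <- which(diff(sign(diff(env))) < 0) + 1L
  r0 <- if (length(pk) >= 2) {
    stats::coef(stats::lm(log(env[pk]) ~ t[pk]))[2]
  } else {
    (log(env[length(env)] + 1e-300) - log(env[1] + 1e-300)) / (t[length(t)] - t[1])
  }
  obj <- function(par) {
    r <- par[1]; w <- par[2]
    X <- cbind(exp(r * t) * cos(w * t), exp(r * t) * sin(w * t))
    fit <- stats::lm.fit(X, b)
    sum(fit$residuals^2)
  }
  best <- stats::optim(c(unname(r0), f0), obj, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-12))
  # also try the non-oscillatory branch
  best0 <- stats::optim(c(unname(r0), 0), obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
  if (best0$value < best$value) best <- best0
  r <- unname(best$par[1]); w <- abs(unname(best$par[2]))
  X <- cbind(exp(r * t) * cos(w * t), exp(r * t) * sin(w * t))
  fit <- stats::lm.fit(X, b)
  list(rate = r, freq = w, fitted = X %*% fit$coefficients,
       r2 = 1 - sum(fit$residuals^2) / sum((b - mean(b))^2))
}
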