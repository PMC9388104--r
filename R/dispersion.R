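#' Vertical decay rates of bulk perturbation modes
#'
#' A lateral perturbation `exp(sigma t + i q y)` of a bulk field decays
#' vertically as `cosh(k (z - H))` with `k^2 = q^2 + (sigma + decay) / Dc`,
#' where `decay` is the linear bulk conversion rate of the field: 0 for
#' total cytosolic MinD (cD) and MinE (cE), and the nucleotide-exchange rate
#' `lam` for MinD-ADP (cDD). The principal square root (`Re k >= 0`) is
#' returned; every place `k` enters the characteristic matrix is through the
#' even combination `k tanh(k H)`, so the branch choice cancels.
#'
#' @param sigma Complex growth rate \[1/s\].
#' @param q Lateral wavenumber \[1/um\].
#' @param p A [min_params()] object.
#' @return A named list of complex vertical wavenumbers `kD`, `kDD`, `kE`
#'   \[1/um\].
#' @export
vertical_decay_rates <- function(sigma, q, p) {
  kD <- sqrt(as.complex(q^2 + sigma / p$Dc))
  kDD <- sqrt(as.complex(q^2 + (sigma + p$lam) / p$Dc))
  list(kD = kD, kDD = kDD, kE = kD)
}

# k * tanh(k H) evaluated from k^2 (even in k, hence branch-free); series
# for small |k H| to avoid cancellation at the origin.
ktanh <- function(k2, H) {
  k <- sqrt(as.complex(k2))
  x <- k * H
  small <- Mod(x) < 1e-4
  out <- k * tanh(x)
  if (any(small)) {
    xs <- x[small]
    out[small] <- (k2[small] * H) * (1 - xs^2 / 3 + 2 * xs^4 / 15)
  }
  out
}

# determinant of a small complex matrix by LU with partial pivoting
det_complex <- function(A) {
  n <- nrow(A)
  d <- 1 + 0i
  for (k in seq_len(n - 1)) {
    piv <- which.max(Mod(A[k:n, k])) + k - 1L
    if (Mod(A[piv, k]) == 0) return(0 + 0i)
    if (piv != k) {
      tmp <- A[k, ]; A[k, ] <- A[piv, ]; A[piv, ] <- tmp
      d <- -d
    }
    d <- d * A[k, k]
    rows <- (k + 1):n
    A[rows, (k + 1):n] <- A[rows, (k + 1):n] -
      (A[rows, k] / A[k, k]) %o% A[k, (k + 1):n]
  }
  d * A[n, n]
}

#' Characteristic matrix of the bulk-surface linearization
#'
#' Assembles the 5 x 5 complex matrix `M(sigma, q)` whose singularity
#' condition `det M = 0` is the exact dispersion relation of a slice about a
#' homogeneous steady state. The unknown vector is
#' `(dmd, dmde, dcD0, dcDD0, dcE0)`. Rows 1-2 are the membrane equations
#' `(sigma + Dm q^2) dm = Jr_m dm + Jr_c dc0`; rows 3-5 are the reactive
#' boundary conditions with the bulk solved exactly by the cosh ansatz (flat
#' no-flux top), `Dc k_j tanh(k_j H) dc_j0 = (Jf_m dm + Jf_c dc0)_j`.
#'
#' @param sigma Complex growth rate \[1/s\].
#' @param q Lateral wavenumber \[1/um\].
#' @param hss One branch row from [solve_hss()] (or any list with `H`,
#'   `md`, `mde`, `cD0`, `cDD0`, `cE0` and residual below `1e-6`).
#' @param p A [min_params()] object.
#' @param jac Optional precomputed [linearized_interface()] Jacobians.
#' @return A complex 5 x 5 matrix.
#' @export
characteristic_matrix <- function(sigma, q, hss, p, jac = NULL) {
  if (!is.null(hss$residual) && hss$residual > 1e-6) {
    stop("characteristic_matrix requires a converged homogeneous steady state")
  }
  if (is.null(jac)) {
    jac <- linearized_interface(hss$cD0, hss$cDD0, hss$cE0,
                                hss$md, hss$mde, p)
  }
  M <- matrix(0 + 0i, 5, 5)
  # membrane rows
  M[1:2, 1:2] <- (sigma + p$Dm * q^2) * diag(2) - jac$Jr_m
  M[1:2, 3:5] <- -jac$Jr_c
  # reactive boundary condition rows (cD, cDD, cE)
  k2 <- c(q^2 + sigma / p$Dc,
          q^2 + (sigma + p$lam) / p$Dc,
          q^2 + sigma / p$Dc)
  kt <- ktanh(k2, hss$H)
  M[3:5, 1:2] <- -jac$Jf_m
  M[3:5, 3:5] <- p$Dc * diag(kt, 3) - jac$Jf_c
  M
}

#' z-discretized linear operator of a slice about a steady state
#'
#' Builds the linear operator governing small lateral-mode perturbations of
#' a slice at wavenumber `q`, with the bulk direction resolved by Chebyshev
#' collocation on `n_nodes` points, and returns its eigenvalues. Boundary
#' conditions (no-flux top, reactive bottom) are eliminated exactly, giving
#' a standard (real, dense) eigenvalue problem on the interior nodes plus
#' the two membrane variables.
#'
#' At coarse resolution this operator supplies physically complete seed sets
#' for the transcendental root finder in [leading_sigma()]; at fine
#' resolution it is an independent cross-check of those roots (collocation
#' converges spectrally, so a few dozen nodes already reach close to machine
#' precision).
#'
#' @inheritParams characteristic_matrix
#' @param n_nodes Number of collocation nodes in z (default 48).
#' @return Complex eigenvalues sorted by decreasing real part.
#' @export
operator_eigenvalues <- function(q, hss, p, n_nodes = 48) {
  cb <- cheb_diff(n_nodes - 1L, hss$H)
  M <- n_nodes
  z <- cb$z; Dz <- cb$D
  Dz2 <- Dz %*% Dz
  jac <- linearized_interface(hss$cD0, hss$cDD0, hss$cE0, hss$md, hss$mde, p)
  nv <- 3L * M + 2L
  idx <- function(f, node) as.integer((f - 1L) * M + node)
  im <- c(idx(1L, 1L), idx(2L, 1L), idx(3L, 1L))       # contact values
  i_md <- 3L * M + 1L; i_mde <- 3L * M + 2L
  decay <- c(0, p$lam, 0)

  A <- matrix(0, nv, nv)        # dynamics rows (only interior + membrane used)
  for (f in 1:3) {
    rows <- idx(f, 2:(M - 1L))
    cols <- idx(f, 1:M)
    A[rows, cols] <- p$Dc * Dz2[2:(M - 1L), ]
    A[cbind(rows, rows)] <- A[cbind(rows, rows)] - p$Dc * q^2 - decay[f]
  }
  A[i_md, c(i_md, i_mde)] <- jac$Jr_m[1, ]
  A[i_mde, c(i_md, i_mde)] <- jac$Jr_m[2, ]
  A[i_md, i_md] <- A[i_md, i_md] - p$Dm * q^2
  A[i_mde, i_mde] <- A[i_mde, i_mde] - p$Dm * q^2
  A[i_md, im] <- jac$Jr_c[1, ]
  A[i_mde, im] <- jac$Jr_c[2, ]

  # six sigma-independent constraints: reactive bottom, no-flux top
  C <- matrix(0, 6, nv)
  for (f in 1:3) {
    # -Dc dz Z_f(0) = Jf_m dm + Jf_c dc0
    C[f, idx(f, 1:M)] <- -p$Dc * Dz[1, ]
    C[f, im] <- C[f, im] - jac$Jf_c[f, ]
    C[f, c(i_md, i_mde)] <- -jac$Jf_m[f, ]
    # dz Z_f(H) = 0
    C[3L + f, idx(f, 1:M)] <- Dz[M, ]
  }
  b_idx <- c(idx(1:3, 1L), idx(1:3, M))                 # eliminated unknowns
  i_idx <- setdiff(seq_len(nv), b_idx)
  Tb <- -solve(C[, b_idx], C[, i_idx])                  # u_b = Tb %*% u_i
  dyn <- c(as.vector(vapply(1:3, function(f) idx(f, 2:(M - 1L)),
                            integer(M - 2L))), i_md, i_mde)
  A_red <- A[dyn, i_idx] + A[dyn, b_idx] %*% Tb
  ev <- eigen(A_red, only.values = TRUE)$values
  ev[order(-Re(ev))]
}

# Chebyshev differentiation matrix on [0, H]; node 1 at z = 0 (membrane),
# node N+1 at z = H. Standard collocation construction with the
# negative-sum trick for the diagonal.
cheb_diff <- function(N, H) {
  stopifnot(N >= 2)
  x <- cos(pi * (0:N) / N)
  c_ <- c(2, rep(1, N - 1), 2) * (-1)^(0:N)
  X <- matrix(x, N + 1, N + 1)
  dX <- X - t(X)
  D <- (c_ %o% (1 / c_)) / (dX + diag(N + 1))
  diag(D) <- diag(D) - rowSums(D)
  # map x in [1, -1] to z in [0, H]
  list(z = H * (1 - x) / 2, D = -(2 / H) * D)
}

#' Leading growth rate at one wavenumber
#'
#' Finds the root of the transcendental dispersion relation
#' `det M(sigma, q) = 0` with the largest real part. Seeds are taken from
#' the caller (continuation in `q`) and, when absent or unconverged, from
#' the leading eigenvalues of the coarse z-discretized operator
#' ([operator_eigenvalues()]); each seed is polished by a damped complex
#' Newton iteration on the row-scaled determinant.
#'
#' @inheritParams characteristic_matrix
#' @param seeds Optional complex vector of starting guesses.
#' @param n_seed_nodes Collocation resolution of the seed operator.
#' @param n_seeds How many leading operator eigenvalues to polish.
#' @param tol Convergence tolerance on the Newton step (relative).
#' @return A list with `sigma` (leading root), `roots` (all distinct
#'   converged roots, sorted by decreasing real part).
#' @export
leading_sigma <- function(q, hss, p, seeds = NULL, n_seed_nodes = 40,
                          n_seeds = 6, tol = 1e-12) {
  jac <- linearized_interface(hss$cD0, hss$cDD0, hss$cE0, hss$md, hss$mde, p)
  roots <- polish_sigma_seeds(q, hss, p, jac, seeds, tol)
  if (length(roots) == 0 || isTRUE(attr(roots, "need_reseed"))) {
    ev <- operator_eigenvalues(q, hss, p, n_nodes = n_seed_nodes)
    ev <- ev[Im(ev) >= -1e-12]          # conjugate partner implied
    roots2 <- polish_sigma_seeds(q, hss, p, jac, ev[seq_len(min(n_seeds, length(ev)))], tol)
    roots <- unique(c(roots, roots2))
  }
  if (length(roots) == 0) {
    stop(sprintf("no dispersion root found at q = %g", q))
  }
  roots <- roots[order(-Re(roots))]
  list(sigma = roots[1], roots = roots)
}

# Newton-polish a set of seeds on the row-scaled determinant; returns the
# distinct converged roots.
polish_sigma_seeds <- function(q, hss, p, jac, seeds, tol) {
  if (is.null(seeds) || length(seeds) == 0) {
    out <- complex(0); attr(out, "need_reseed") <- TRUE
    return(out)
  }
  # sigma-independent row scaling chosen once per call
  M0 <- characteristic_matrix(seeds[1], q, hss, p, jac)
  rs <- apply(Mod(M0), 1, max)
  rs[rs == 0] <- 1
  fdet <- function(s) det_complex(characteristic_matrix(s, q, hss, p, jac) / rs)
  roots <- complex(0)
  for (s0 in seeds) {
    s <- as.complex(s0)
    ok <- FALSE
    for (it in 1:60) {
      h <- 1e-7 * (1 + Mod(s))
      f <- fdet(s)
      df <- (fdet(s + h) - fdet(s - h)) / (2 * h)
      if (!is.finite(Mod(df)) || Mod(df) == 0) break
      step <- f / df
      # damp very large steps
      if (Mod(step) > 0.5 * (1 + Mod(s))) step <- step * 0.5 * (1 + Mod(s)) / Mod(step)
      s <- s - step
      if (Mod(step) < tol * (1 + Mod(s))) { ok <- TRUE; break }
    }
    if (ok && is.finite(Mod(s)) && Mod(fdet(s)) < 1e-8) {
      if (!length(roots) || min(Mod(roots - s)) > 1e-8 * (1 + Mod(s))) {
        roots <- c(roots, s)
      }
    }
  }
  roots
}

#' Default wavenumber grid for dispersion relations
#'
#' Log-spaced lateral wavenumbers covering the physically relevant band of
#' the Min system (pattern wavelengths of a few to a few hundred um).
#'
#' @param q_min,q_max Grid limits \[1/um\].
#' @param n Number of points.
#' @return Increasing numeric vector.
#' @export
default_q_grid <- function(q_min = 1e-3, q_max = 2, n = 120) {
  exp(seq(log(q_min), log(q_max), length.out = n))
}

#' Dispersion relation of a slice steady state
#'
#' Traces the leading complex growth rate `sigma(q)` over a wavenumber grid
#' by continuation (the root at each grid point seeds the next, with
#' periodic and on-demand re-seeding from the discretized-operator
#' eigenvalues), then extracts the fastest-growing mode `q_star` (parabolic
#' refinement of `Re sigma` about the grid maximum), the right edge of the
#' unstable band `q_max` (bisection on `Re sigma`), the mode ratio
#' `q_max / q_star`, and whether the leading mode is oscillatory
#' (`Im sigma(q_star) != 0`). If `Re sigma <= 0` over the whole grid the
#' curve is flagged laterally stable and the ratio is undefined (`NA`).
#'
#' @inheritParams characteristic_matrix
#' @param q_grid Increasing grid of wavenumbers (default
#'   [default_q_grid()]).
#' @param reseed_every Re-seed from the operator every this many grid
#'   points (guards against branch swaps during continuation).
#' @param n_seed_nodes Collocation resolution used for (re-)seeding.
#' @return A tibble of class `dispersion_curve` with columns `q`,
#'   `re_sigma`, `im_sigma`, and attributes `q_star`, `q_max`, `ratio`,
#'   `oscillatory`, `unstable`, `sigma_star`, `hss`.
#' @examples
#' \donttest{
#' p <- default_min_params()
#' hss <- solve_hss(5, 665, 410, p)[1, ]
#' dc <- dispersion_curve(hss, p, q_grid = default_q_grid(n = 40))
#' glance(dc)
#' }
#' @export
dispersion_curve <- function(hss, p, q_grid = default_q_grid(),
                             reseed_every = 15, n_seed_nodes = 40) {
  stopifnot(all(diff(q_grid) > 0))
  nq <- length(q_grid)
  sig <- complex(nq)
  prev <- NULL
  for (i in seq_len(nq)) {
    force_reseed <- (i %% reseed_every == 1L)
    seeds <- if (!is.null(prev) && !force_reseed) prev else NULL
    ls <- leading_sigma(q_grid[i], hss, p, seeds = seeds,
                        n_seed_nodes = n_seed_nodes)
    s <- ls$sigma
    if (!is.null(prev) &&
        Mod(s - prev[1]) > 0.25 * (1 + Mod(prev[1])) && !force_reseed) {
      # suspicious jump: re-seed from the operator and keep the best
      ls2 <- leading_sigma(q_grid[i], hss, p, seeds = NULL,
                           n_seed_nodes = n_seed_nodes)
      if (Re(ls2$sigma) > Re(s)) { ls <- ls2; s <- ls2$sigma }
    }
    sig[i] <- s
    prev <- unique(c(s, ls$roots[seq_len(min(3, length(ls$roots)))]))
  }

  out <- tibble::tibble(q = q_grid, re_sigma = Re(sig), im_sigma = Im(sig))
  re <- Re(sig)
  unstable <- any(re > 0)
  q_star <- q_max <- ratio <- sigma_star <- NA
  oscillatory <- NA
  if (unstable) {
    i0 <- which.max(re)
    q_star <- q_grid[i0]
    sigma_star <- sig[i0]
    if (i0 > 1 && i0 < nq) {
      # parabolic refinement of Re sigma(q) about the grid maximum
      qs <- q_grid[(i0 - 1):(i0 + 1)]; rs <- re[(i0 - 1):(i0 + 1)]
      denom <- (qs[1] - qs[2]) * (qs[1] - qs[3]) * (qs[2] - qs[3])
      a <- (qs[3] * (rs[2] - rs[1]) + qs[2] * (rs[1] - rs[3]) +
              qs[1] * (rs[3] - rs[2])) / denom
      b <- (qs[3]^2 * (rs[1] - rs[2]) + qs[2]^2 * (rs[3] - rs[1]) +
              qs[1]^2 * (rs[2] - rs[3])) / denom
      if (a < 0) {
        q_ref <- -b / (2 * a)
        if (q_ref > qs[1] && q_ref < qs[3]) {
          ls <- leading_sigma(q_ref, hss, p, seeds = sig[i0])
          if (Re(ls$sigma) >= re[i0]) { q_star <- q_ref; sigma_star <- ls$sigma }
        }
      }
    }
    oscillatory <- abs(Im(sigma_star)) > 1e-8
    # right band edge by bisection between last unstable and next stable point
    iu <- max(which(re > 0))
    if (iu == nq) {
      q_max <- NA  # band extends beyond the grid
      warning("unstable band extends beyond the q grid; q_max undefined")
    } else {
      f <- function(qq) {
        Re(leading_sigma(qq, hss, p, seeds = sig[c(iu, iu + 1)])$sigma)
      }
      q_max <- stats::uniroot(f, c(q_grid[iu], q_grid[iu + 1]),
                              f.lower = re[iu], f.upper = re[iu + 1],
                              tol = 1e-6 * q_grid[iu])$root
      ratio <- q_max / q_star
    }
  }
  hss$stable_local <- !unstable
  structure(out,
            class = c("dispersion_curve", class(out)),
            q_star = q_star, q_max = q_max, ratio = ratio,
            oscillatory = oscillatory, unstable = unstable,
            sigma_star = sigma_star, hss = hss)
}

#' @export
print.dispersion_curve <- function(x, ...) {
  cat("Dispersion curve over", nrow(x), "wavenumbers\n")
  if (isTRUE(attr(x, "unstable"))) {
    cat(sprintf("  q* = %.5g, q_max = %.5g, ratio = %.4g, oscillatory = %s\n",
                attr(x, "q_star"), attr(x, "q_max"), attr(x, "ratio"),
                attr(x, "oscillatory")))
  } else {
    cat("  no lateral instability\n")
  }
  invisible(x)
}
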