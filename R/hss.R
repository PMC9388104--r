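#' Steady-state membrane flux of MinD-ADP into the bulk
#'
#' At a laterally homogeneous steady state the only nonzero boundary flux is
#' the release of MinD-ADP, which diffuses into the bulk and decays (by
#' nucleotide exchange at rate `lam`) back into MinD-ATP. Solving the
#' stationary bulk problem `Dc c'' = lam c` on `[0, H]` with a no-flux top
#' yields the closed form
#' `phi = sqrt(Dc * lam) * tanh(sqrt(lam / Dc) * H) * cDD0`.
#' The flux grows monotonically with bulk height and saturates at
#' `sqrt(Dc * lam) * cDD0` once `H` exceeds the boundary-layer scale
#' `sqrt(Dc / lam)`.
#'
#' @param cDD0 MinD-ADP contact concentration at z = 0 \[1/um^3\].
#' @param H Bulk height \[um\].
#' @param p A [min_params()] object.
#' @return Flux \[1/(um^2 s)\]; vectorized over `cDD0` and `H`.
#' @export
steady_flux_phi <- function(cDD0, H, p) {
  if (any(H <= 0)) stop("bulk height H must be positive")
  if (any(cDD0 < 0)) stop("cDD0 must be non-negative")
  sqrt(p$Dc * p$lam) * tanh(sqrt(p$lam / p$Dc) * H) * cDD0
}

# Stationary interface state as a closed-form function of md.
#
# At an HSS, mde, cE0, cD0 and cDD0 all follow from md:
#   mde  : MinE recruitment balance  kdE md (nE - mde/H) = kde mde
#   cE0  : MinE mass constraint
#   cD0  : MinD mass constraint
#   cDD0 : flux balance  kde mde = phi(cDD0, H)
# which leaves one scalar equation, the md balance rDon = rEon.
hss_from_md <- function(md, H, nD, nE, p, gamH = NULL) {
  if (is.null(gamH)) gamH <- sqrt(p$Dc * p$lam) * tanh(sqrt(p$lam / p$Dc) * H)
  mde <- p$kdE * md * nE / (p$kde + p$kdE * md / H)
  cE0 <- nE - mde / H
  cD0 <- nD - (md + mde) / H
  cDD0 <- p$kde * mde / gamH
  list(md = md, mde = mde, cD0 = cD0, cDD0 = cDD0, cE0 = cE0)
}

# The remaining scalar stationarity condition rDon - rEon = 0 as a function
# of md (vectorized).
hss_gap <- function(md, H, nD, nE, p, gamH = NULL) {
  s <- hss_from_md(md, H, nD, nE, p, gamH)
  (p$kD + p$kdD * md) * (s$cD0 - s$cDD0) - p$kdE * md * s$cE0
}

#' Residual of a candidate homogeneous steady state
#'
#' Evaluates the five stationarity conditions of a slice: the two membrane
#' reaction balances, the MinD-ADP flux balance against [steady_flux_phi()],
#' and the two mass-conservation constraints
#' `cD0 + (md + mde)/H = nD`, `cE0 + mde/H = nE`. The cD and cE components
#' of the boundary flux vanish identically when the first two components do,
#' so they are implied rather than listed.
#'
#' @param hss A list or one-row data frame with fields `H`, `nD`, `nE`,
#'   `md`, `mde`, `cD0`, `cDD0`, `cE0`.
#' @param p A [min_params()] object.
#' @return Numeric vector of length 5; all zeros iff `hss` is a homogeneous
#'   steady state.
#' @export
hss_residual <- function(hss, p) {
  r <- reaction_rates(cDT = hss$cD0 - hss$cDD0, cE = hss$cE0,
                      md = hss$md, mde = hss$mde, p = p)
  phi <- steady_flux_phi(hss$cDD0, hss$H, p)
  c(
    md_balance  = r$rDon - r$rEon,
    mde_balance = r$rEon - r$rDEoff,
    flux_cDD    = r$rDEoff - phi,
    mass_D      = hss$cD0 + (hss$md + hss$mde) / hss$H - hss$nD,
    mass_E      = hss$cE0 + hss$mde / hss$H - hss$nE
  )
}

#' Homogeneous steady states of a slice
#'
#' Solves for all laterally homogeneous steady states of a rectangular slice
#' of bulk height `H` with slice total densities `nD`, `nE`. The five
#' stationarity conditions reduce exactly to one scalar equation in the
#' membrane MinD density `md` (see [hss_residual()] for the full system), so
#' branches are found by a dense bracketed scan over the admissible interval
#' `md in [0, md_max]` followed by high-precision root refinement.
#' Generically there are one or three branches (a saddle-node pair appears
#' and disappears as the conserved masses or the height vary).
#'
#' The zero-MinD and zero-MinE corners are handled analytically: without
#' MinD everything sits in the cytosol (`cE0 = nE`), and without MinE there
#' is no detachment pathway so all MinD accumulates on the membrane
#' (`md = nD * H`).
#'
#' @param H Bulk height of the slice \[um\].
#' @param nD,nE Slice total densities of MinD and MinE \[1/um^3\].
#' @param p A [min_params()] object.
#' @param init_hint Optional list with `md` and `mde` (or a previous branch
#'   row); the returned branch nearest the hint is flagged in the
#'   `nearest_hint` column.
#' @param n_scan Number of scan points for bracketing (default 400).
#' @return A tibble of class `hss_branch_set`, one row per branch, sorted by
#'   `cD0`, with columns `branch_id`, `H`, `nD`, `nE`, `md`, `mde`, `cD0`,
#'   `cDD0`, `cE0`, `phi`, `residual` (max-norm of [hss_residual()]),
#'   `stable_local` (filled by the dispersion module, `NA` here) and
#'   `nearest_hint`.
#' @examples
#' p <- default_min_params()
#' solve_hss(H = 5, nD = 665, nE = 410, p = p)
#' @export
solve_hss <- function(H, nD, nE, p, init_hint = NULL, n_scan = 400) {
  stopifnot(H > 0, nD >= 0, nE >= 0)
  make_row <- function(md, mde, cD0, cDD0, cE0) {
    row <- list(H = H, nD = nD, nE = nE, md = md, mde = mde,
                cD0 = cD0, cDD0 = cDD0, cE0 = cE0)
    row$phi <- steady_flux_phi(cDD0, H, p)
    row$residual <- max(abs(hss_residual(row, p)))
    tibble::as_tibble(row)
  }

  if (nD == 0) {
    out <- make_row(0, 0, 0, 0, nE)
  } else if (nE == 0) {
    out <- make_row(nD * H, 0, 0, 0, 0)
  } else {
    # admissible md range: total membrane MinD cannot exceed the slice total
    md_cap <- function(md) md + hss_from_md(md, H, nD, nE, p)$mde - nD * H
    md_max <- stats::uniroot(md_cap, c(0, nD * H), tol = 1e-14 * nD * H)$root
    grid <- md_max * seq(0, 1, length.out = n_scan)^2  # refine near md = 0
    g <- hss_gap(grid, H, nD, nE, p)
    roots <- numeric(0)
    sgn <- sign(g)
    idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
    for (i in idx) {
      r <- stats::uniroot(hss_gap, c(grid[i], grid[i + 1]),
                          H = H, nD = nD, nE = nE, p = p,
                          tol = .Machine$double.eps)$root
      roots <- c(roots, r)
    }
    roots <- c(roots, grid[which(g == 0)])
    # endpoint root (all MinD on the membrane) only occurs at nE = 0
    if (length(roots) == 0) {
      stop(sprintf("no homogeneous steady state found for H=%g, nD=%g, nE=%g",
                   H, nD, nE))
    }
    # merge duplicates at relative tolerance 1e-6
    roots <- sort(unique(roots))
    keep <- c(TRUE, diff(roots) > 1e-6 * pmax(roots[-1], 1e-12))
    roots <- roots[keep]
    out <- dplyr::bind_rows(lapply(roots, function(md) {
      s <- hss_from_md(md, H, nD, nE, p)
      make_row(s$md, s$mde, s$cD0, s$cDD0, s$cE0)
    }))
  }

  out <- out[order(out$cD0), ]
  out$branch_id <- seq_len(nrow(out))
  out$stable_local <- NA
  out$nearest_hint <- FALSE
  if (!is.null(init_hint)) {
    d <- (out$md - init_hint$md)^2 + (out$mde - init_hint$mde)^2
    out$nearest_hint[which.min(d)] <- TRUE
  }
  class(out) <- c("hss_branch_set", class(out))
  out
}

#' Continuation of steady-state branches along a parameter path
#'
#' Solves [solve_hss()] along a sequence of `(H, nD, nE)` points and
#' propagates branch identities by nearest-neighbour matching in
#' `(md, mde, cD0, cE0)` space. Fold points -- path intervals across which
#' the branch count changes -- are reported with their bracketing indices.
#' Matching ties are broken by `cD0` ordering (and logged as a warning).
#'
#' @param path A data frame with columns `H`, `nD`, `nE` (one row per path
#'   point).
#' @param p A [min_params()] object.
#' @return A list with `sets` (list of `hss_branch_set` tibbles, each with an
#'   extra `track_id` column) and `folds` (tibble with `i_before`, `i_after`,
#'   `count_before`, `count_after`).
#' @export
hss_continuation <- function(path, p) {
  stopifnot(all(c("H", "nD", "nE") %in% names(path)))
  sets <- vector("list", nrow(path))
  folds <- list()
  next_track <- 1L
  prev <- NULL
  for (i in seq_len(nrow(path))) {
    s <- solve_hss(path$H[i], path$nD[i], path$nE[i], p)
    if (is.null(prev)) {
      s$track_id <- seq_len(nrow(s))
      next_track <- nrow(s) + 1L
    } else {
      s$track_id <- NA_integer_
      # greedy nearest-neighbour matching, closest pairs first
      d <- outer(seq_len(nrow(s)), seq_len(nrow(prev)), function(a, b) {
        sqrt((s$md[a] - prev$md[b])^2 + (s$mde[a] - prev$mde[b])^2 +
               (s$cD0[a] - prev$cD0[b])^2 + (s$cE0[a] - prev$cE0[b])^2)
      })
      while (any(is.finite(d))) {
        j <- arrayInd(which.min(d), dim(d))
        ties <- which(abs(d - d[j]) < 1e-12 * (1 + d[j]))
        if (length(ties) > 1) {
          warning("ambiguous branch match; tie broken by cD0 ordering")
        }
        s$track_id[j[1]] <- prev$track_id[j[2]]
        d[j[1], ] <- Inf
        d[, j[2]] <- Inf
      }
      new_idx <- which(is.na(s$track_id))
      if (length(new_idx)) {
        s$track_id[new_idx] <- seq(next_track, length.out = length(new_idx))
        next_track <- next_track + length(new_idx)
      }
      if (nrow(s) != nrow(prev)) {
        folds[[length(folds) + 1L]] <- tibble::tibble(
          i_before = i - 1L, i_after = i,
          count_before = nrow(prev), count_after = nrow(s)
        )
      }
    }
    sets[[i]] <- s
    prev <- s
  }
  list(
    sets = sets,
    folds = if (length(folds)) dplyr::bind_rows(folds) else
      tibble::tibble(i_before = integer(), i_after = integer(),
                     count_before = integer(), count_after = integer())
  )
}
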