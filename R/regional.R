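#' Spatial averaging operators for wedge fields
#'
#' Trapezoidal implementations of the four averaging operators used
#' throughout: the membrane average `<.>_S` (scalar), the bulk average
#' `<.>_V` weighted by the local column height (scalar), the lateral
#' average `<.>_y` (profile over x), and the slice average `<.>_{y,z}`
#' (profile over x). Bulk fields are sampled on terrain-following grids:
#' the third index runs over `zeta in [0, 1]` with physical height
#' `z = zeta * H(x)`, so every column is resolved from membrane to top
#' regardless of the wedge incline.
#'
#' @param field For `average_membrane`/`average_y`: a matrix indexed
#'   \[x, y\]. For `average_bulk`/`average_yz`: a 3-d array indexed
#'   \[x, y, zeta\].
#' @param x,y,zeta Grid vectors (increasing); `zeta` in \[0, 1\].
#' @param geometry A [wedge_geometry()] (supplies `H(x)` and `|V|`).
#' @return A scalar (`average_membrane`, `average_bulk`) or a numeric
#'   profile over `x` (`average_y`, `average_yz`).
#' @name averaging
NULL

trapz_weights <- function(g) {
  n <- length(g)
  if (n == 1) return(1)
  w <- c(diff(g) / 2, 0) + c(0, diff(g) / 2)
  w
}

#' @rdname averaging
#' @export
average_membrane <- function(field, x, y) {
  stopifnot(nrow(field) == length(x), ncol(field) == length(y))
  wx <- trapz_weights(x); wy <- trapz_weights(y)
  sum((wx %o% wy) * field) / (sum(wx) * sum(wy))
}

#' @rdname averaging
#' @export
average_bulk <- function(field, x, y, zeta, geometry) {
  stopifnot(length(dim(field)) == 3,
            dim(field)[1] == length(x), dim(field)[2] == length(y),
            dim(field)[3] == length(zeta))
  H <- geometry$H(x)
  wx <- trapz_weights(x); wy <- trapz_weights(y); wz <- trapz_weights(zeta)
  # int_0^{H(x)} dz = H(x) int_0^1 dzeta on the terrain-following grid
  col <- apply(sweep(field, 3, wz, "*"), c(1, 2), sum)   # <.> over zeta
  num <- sum((wx * H) %o% wy * col)
  den <- sum(wx * H) * sum(wy)
  # normalization by the true wedge volume of the sampled region
  num / den
}

#' @rdname averaging
#' @export
average_y <- function(field, x, y) {
  stopifnot(nrow(field) == length(x), ncol(field) == length(y))
  wy <- trapz_weights(y)
  as.vector(field %*% wy) / sum(wy)
}

#' @rdname averaging
#' @export
average_yz <- function(field, x, y, zeta, geometry) {
  stopifnot(length(dim(field)) == 3)
  wy <- trapz_weights(y); wz <- trapz_weights(zeta)
  prof <- apply(sweep(sweep(field, 2, wy, "*"), 3, wz, "*"), 1, sum)
  prof / (sum(wy) * sum(wz))
}

#' Instantaneous total densities at the membrane
#'
#' Since only cytosolic proteins close to the membrane take part in the
#' membrane kinetics, the instantaneous membrane-proximal total densities
#' combine the membrane-bound mass (converted to a volume density with the
#' local column height) with the contact concentrations:
#' `nD_tilde = (md + mde)/H(x) + cD|z=0` and
#' `nE_tilde = mde/H(x) + cE|z=0`. At a slice HSS these reduce exactly to
#' the slice totals `nD`, `nE` (the stationary cD and cE are z-uniform).
#'
#' @param md,mde Membrane density matrices indexed \[x, y\].
#' @param cD0,cE0 Contact concentration matrices indexed \[x, y\].
#' @param x Grid along the wedge axis.
#' @param geometry A [wedge_geometry()].
#' @return A list with matrices `nD` and `nE` indexed \[x, y\].
#' @export
instantaneous_totals <- function(md, mde, cD0, cE0, x, geometry) {
  H <- geometry$H(x)
  if (any(H <= 0)) stop("bulk height must be positive on the grid")
  list(
    nD = (md + mde) / H + cD0,
    nE = mde / H + cE0
  )
}

#' Pattern classes of the commensurability criterion
#'
#' The empirical commensurability criterion maps the mode ratio
#' `q_max / q_star` of a dispersion relation to the fully developed pattern
#' type: no unstable band gives `STABLE`; a ratio below 2 marks
#' spatiotemporal chaos (`CHAOS`); ordered patterns appear above 2, with
#' standing waves (`SW`) close to the transition and traveling waves (`TW`)
#' farther from it. The SW/TW boundary has no sharp criterion, so it is a
#' configurable threshold (default 2.5) and the continuous ratio is always
#' carried alongside the class.
#'
#' @param curve A [dispersion_curve()], or a bare numeric ratio.
#' @param thresholds List with `r_chaos` (default 2) and `r_TW` (default
#'   2.5).
#' @return A factor of class level in `c("STABLE", "CHAOS", "SW", "TW")`
#'   with attribute `score` (the continuous ratio, `NA` when stable).
#' @export
classify_ratio <- function(curve, thresholds = list(r_chaos = 2, r_TW = 2.5)) {
  lv <- c("STABLE", "CHAOS", "SW", "TW")
  if (inherits(curve, "dispersion_curve")) {
    ratio <- attr(curve, "ratio")
    unstable <- isTRUE(attr(curve, "unstable"))
  } else {
    ratio <- as.numeric(curve)
    unstable <- is.finite(ratio)
  }
  cls <- if (!unstable || !is.finite(ratio)) "STABLE"
    else if (ratio < thresholds$r_chaos) "CHAOS"
    else if (ratio < thresholds$r_TW) "SW"
    else "TW"
  structure(factor(cls, levels = lv), score = if (cls == "STABLE") NA_real_ else ratio)
}

#' Regional pattern-type kymograph from slice-averaged densities
#'
#' The central pipeline: for every cell of an `(x, t)` grid of
#' slice-averaged total densities, solve the local homogeneous steady state
#' (branch chosen by continuation in time at fixed x), compute the regional
#' dispersion relation `sigma(q; H(x), nD(x,t), nE(x,t))`, extract the mode
#' ratio, and classify the expected local pattern. The critical position
#' `x_crit(t)` where the ratio crosses 2 is interpolated linearly between
#' grid points; all crossings are reported and the primary one is the
#' crossing that separates the largest connected sub-threshold region from
#' the largest connected ordered region.
#'
#' Homogeneous steady states and dispersion curves are cached keyed by
#' `(H, nD, nE)` rounded to 4 significant digits, which keeps long runs with
#' slowly varying densities inexpensive.
#'
#' @param nD,nE Matrices of slice totals indexed \[x, t\] \[1/um^3\].
#' @param x Positions along the wedge \[um\].
#' @param t Times \[s\].
#' @param geometry A [wedge_geometry()].
#' @param p A [min_params()] object.
#' @param q_grid Wavenumber grid for the regional dispersion relations.
#' @param thresholds Classifier thresholds, see [classify_ratio()].
#' @return A tibble of class `regional_kymograph` with columns `x`, `t`,
#'   `H`, `nD`, `nE`, `ratio`, `class`, and attribute `x_crit` (tibble with
#'   `t`, `x_crit`, `n_crossings`).
#' @export
regional_kymograph <- function(nD, nE, x, t, geometry, p,
                               q_grid = default_q_grid(n = 60),
                               thresholds = list(r_chaos = 2, r_TW = 2.5)) {
  stopifnot(all(dim(nD) == c(length(x), length(t))),
            all(dim(nD) == dim(nE)))
  H <- geometry$H(x)
  cache <- new.env(parent = emptyenv())
  prev_branch <- vector("list", length(x))
  cells <- vector("list", length(x) * length(t))
  k <- 0L
  for (j in seq_along(t)) {
    for (i in seq_along(x)) {
      k <- k + 1L
      key <- paste(signif(H[i], 4), signif(nD[i, j], 4), signif(nE[i, j], 4),
                   sep = "|")
      hit <- get0(key, envir = cache)
      if (is.null(hit)) {
        hit <- tryCatch({
          bs <- solve_hss(H[i], nD[i, j], nE[i, j], p,
                          init_hint = prev_branch[[i]])
          row <- if (any(bs$nearest_hint)) bs[bs$nearest_hint, ] else bs[1, ]
          dcv <- dispersion_curve(row, p, q_grid = q_grid)
          list(row = row, ratio = attr(dcv, "ratio"),
               unstable = attr(dcv, "unstable"))
        }, error = function(e) NULL)
        assign(key, if (is.null(hit)) list(failed = TRUE) else hit,
               envir = cache)
      }
      if (is.null(hit) || isTRUE(hit$failed)) {
        cells[[k]] <- tibble::tibble(x = x[i], t = t[j], H = H[i],
                                     nD = nD[i, j], nE = nE[i, j],
                                     ratio = NA_real_, class = "FAILED")
        next
      }
      prev_branch[[i]] <- hit$row
      cls <- classify_ratio(if (hit$unstable) hit$ratio else NA_real_,
                            thresholds)
      cells[[k]] <- tibble::tibble(x = x[i], t = t[j], H = H[i],
                                   nD = nD[i, j], nE = nE[i, j],
                                   ratio = hit$ratio,
                                   class = as.character(cls))
    }
  }
  out <- dplyr::bind_rows(cells)
  xc <- dplyr::bind_rows(lapply(seq_along(t), function(j) {
    sub <- out[out$t == t[j], ]
    xing <- ratio_crossings(sub$x, sub$ratio, level = thresholds$r_chaos)
    tibble::tibble(t = t[j], x_crit = xing$primary,
                   n_crossings = length(xing$all))
  }))
  structure(out, class = c("regional_kymograph", class(out)), x_crit = xc,
            thresholds = thresholds)
}

# All x positions where a ratio profile crosses `level` (linear
# interpolation), and the primary crossing: the one separating the largest
# connected below-level region from the largest connected above-level
# region (sum of flanking region lengths is maximized).
ratio_crossings <- function(x, ratio, level = 2) {
  ok <- is.finite(ratio)
  xs <- x[ok]; rs <- ratio[ok]
  if (length(xs) < 2) return(list(all = numeric(0), primary = NA_real_))
  d <- rs - level
  idx <- which(d[-1] * d[-length(d)] < 0)
  all_x <- vapply(idx, function(i) {
    xs[i] + (xs[i + 1] - xs[i]) * d[i] / (d[i] - d[i + 1])
  }, numeric(1))
  all_x <- c(all_x, xs[which(d == 0)])
  if (length(all_x) == 0) return(list(all = numeric(0), primary = NA_real_))
  all_x <- sort(all_x)
  # score each crossing by the extents of the CONTIGUOUS below-level and
  # above-level runs that it separates
  sgn <- d > 0
  run_id <- cumsum(c(1L, as.integer(diff(sgn) != 0)))
  run_len <- vapply(split(xs, run_id), function(v) diff(range(c(v, v))),
                    numeric(1))
  score <- vapply(all_x, function(xc) {
    i <- max(which(xs <= xc))
    left <- run_len[[as.character(run_id[i])]]
    right <- if (i < length(xs)) run_len[[as.character(run_id[i + 1])]] else 0
    left + right
  }, numeric(1))
  list(all = all_x, primary = all_x[which.max(score)])
}
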