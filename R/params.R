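#' Kinetic and transport parameters of the Min skeleton model
#'
#' Bundles the nine parameters of the MinD/MinE skeleton model: bulk and
#' membrane diffusion constants, the four membrane kinetic rates, the
#' cytosolic nucleotide-exchange rate, and the global average total densities
#' of MinD and MinE. Units are fixed to micrometres and seconds throughout
#' the package: bulk densities in 1/um^3, membrane densities in 1/um^2.
#'
#' @param Dc Bulk (cytosolic) diffusion constant \[um^2/s\].
#' @param Dm Membrane diffusion constant \[um^2/s\].
#' @param kD MinD attachment rate \[um/s\].
#' @param kdD MinD self-recruitment rate \[um^3/s\].
#' @param kdE MinE recruitment rate \[um^3/s\].
#' @param kde MinDE complex dissociation rate \[1/s\].
#' @param lam Nucleotide exchange rate (MinD-ADP -> MinD-ATP) \[1/s\].
#' @param nD_bar Average total MinD density \[1/um^3\].
#' @param nE_bar Average total MinE density \[1/um^3\].
#'
#' @return An object of class `min_params` (a named list of the nine values).
#' @seealso [default_min_params()] for the canonical in vitro parameter set.
#' @export
min_params <- function(Dc, Dm, kD, kdD, kdE, kde, lam, nD_bar, nE_bar) {
  p <- list(Dc = Dc, Dm = Dm, kD = kD, kdD = kdD, kdE = kdE, kde = kde,
            lam = lam, nD_bar = nD_bar, nE_bar = nE_bar)
  vals <- unlist(p)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all Min model parameters must be finite and strictly positive")
  }
  structure(p, class = "min_params")
}

#' Canonical Min model parameter set
#'
#' The parameter values used throughout for the reconstituted (in vitro) Min
#' system: fast bulk diffusion (60 um^2/s) against slow membrane diffusion
#' (0.013 um^2/s), total densities 665 (MinD) and 410 (MinE) per um^3, and
#' nucleotide exchange at 6/s. Shipped as a YAML fixture in
#' `inst/extdata/min_params.yaml`; this constructor reads that file so the
#' serialized record and the in-code default cannot drift apart.
#'
#' @return A `min_params` object.
#' @export
default_min_params <- function() {
  read_min_params(system.file("extdata", "min_params.yaml", package = "minscale"))
}

#' @export
print.min_params <- function(x, ...) {
  cat("Min skeleton model parameters (um, s):\n")
  for (nm in names(x)) cat(sprintf("  %-7s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Wedge geometry with linearly increasing bulk height
#'
#' A rectangular membrane of lateral size `L` x `L` at z = 0, below a bulk
#' whose height grows affinely from `H0` at x = 0 to `H1` at x = L. The
#' height profile H(x) = H0 + (H1 - H0) x / L makes bulk height a spatially
#' graded control parameter. Membrane area is L^2 and bulk volume
#' L^2 (H0 + H1) / 2.
#'
#' @param L Lateral length \[um\].
#' @param H0 Bulk height at x = 0 \[um\].
#' @param H1 Bulk height at x = L \[um\].
#' @return An object of class `wedge_geometry` with fields `L`, `H0`, `H1`,
#'   the height function `H(x)`, membrane area `area` and bulk volume
#'   `volume`.
#' @examples
#' w <- wedge_geometry(L = 500, H0 = 5, H1 = 50)
#' w$H(c(0, 250, 500))
#' @export
wedge_geometry <- function(L, H0 = 5, H1 = 50) {
  stopifnot(L > 0, H0 > 0, H0 <= H1)
  force(L); force(H0); force(H1)
  structure(list(
    L = L, H0 = H0, H1 = H1,
    H = function(x) H0 + (H1 - H0) * x / L,
    area = L^2,
    volume = L^2 * (H0 + H1) / 2
  ), class = "wedge_geometry")
}

#' @export
print.wedge_geometry <- function(x, ...) {
  cat(sprintf("Wedge geometry: L = %g um, H(x) from %g to %g um\n",
              x$L, x$H0, x$H1))
  cat(sprintf("  membrane area %g um^2, bulk volume %g um^3\n",
              x$area, x$volume))
  invisible(x)
}

#' Default wedge used for the canonical runs
#'
#' Lateral length 500 um with bulk height ramping from 5 um to 50 um.
#' @return A `wedge_geometry`.
#' @export
default_wedge <- function() wedge_geometry(L = 500, H0 = 5, H1 = 50)

# Convert between the physical cytosol variables (cDD, cDT, cE) and the
# transformed set (cD = cDD + cDT, cDD, cE) in which the bulk PDEs decouple.
# The transformed set is the canonical internal representation.

#' Cytosol variable conversions
#'
#' The bulk dynamics are analysed in the transformed variables
#' (cD, cDD, cE) with cD = cDD + cDT the total cytosolic MinD; in this set
#' the three bulk PDEs decouple (nucleotide exchange only appears as a decay
#' of cDD). These helpers convert a contact-concentration triple between the
#' physical set (cDD, cDT, cE) and the transformed set.
#'
#' @param cDD,cDT,cE,cD Contact concentrations \[1/um^3\]; vectors allowed.
#' @return A named list with the converted triple.
#' @export
contact_to_transformed <- function(cDD, cDT, cE) {
  list(cD = cDD + cDT, cDD = cDD, cE = cE)
}

#' @rdname contact_to_transformed
#' @export
transformed_to_contact <- function(cD, cDD, cE) {
  list(cDD = cDD, cDT = cD - cDD, cE = cE)
}
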