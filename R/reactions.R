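#' Membrane reaction fluxes of the Min skeleton model
#'
#' Evaluates the three elementary membrane reaction fluxes at given
#' membrane-contact cytosol concentrations and membrane densities:
#' cooperative MinD attachment `rDon = (kD + kdD * md) * cDT`, MinE
#' recruitment by membrane-bound MinD `rEon = kdE * md * cE`, and MinDE
#' complex dissociation `rDEoff = kde * mde`. All fluxes are per membrane
#' area and time \[1/(um^2 s)\]. Inputs may be vectors of common length.
#'
#' @param cDT MinD-ATP contact concentration at z = 0 \[1/um^3\].
#' @param cE MinE contact concentration at z = 0 \[1/um^3\].
#' @param md Membrane-bound MinD density \[1/um^2\].
#' @param mde Membrane-bound MinDE complex density \[1/um^2\].
#' @param p A [min_params()] object.
#' @return A named list with components `rDon`, `rEon`, `rDEoff`.
#' @examples
#' p <- default_min_params()
#' reaction_rates(cDT = 1, cE = 1, md = 1, mde = 1, p = p)
#' @export
reaction_rates <- function(cDT, cE, md, mde, p) {
  if (any(c(cDT, cE, md, mde) < 0)) {
    stop("concentrations and membrane densities must be non-negative")
  }
  list(
    rDon   = (p$kD + p$kdD * md) * cDT,
    rEon   = p$kdE * md * cE,
    rDEoff = p$kde * mde
  )
}

#' Reactive rates of change of the membrane densities
#'
#' The reaction part of the membrane dynamics: d(md)/dt gains attached MinD
#' and loses it to MinE recruitment (md -> mde), d(mde)/dt gains from MinE
#' recruitment and loses dissociating complexes. The sum of the two
#' components equals `rDon - rDEoff`, the net change of total membrane-bound
#' MinD.
#'
#' @inheritParams reaction_rates
#' @return A named list with components `md` and `mde` \[1/(um^2 s)\].
#' @export
membrane_rhs_reactions <- function(cDT, cE, md, mde, p) {
  r <- reaction_rates(cDT, cE, md, mde, p)
  list(md = r$rDon - r$rEon, mde = r$rEon - r$rDEoff)
}

#' Boundary fluxes into the bulk at the membrane
#'
#' Net diffusive fluxes into the bulk induced by membrane attachment and
#' detachment, in the transformed cytosol variables (cD, cDD, cE). The sign
#' convention is flux INTO the bulk, so the reactive boundary condition reads
#' `-Dc dz c |_{z=0} = f` and interface mass bookkeeping is a literal
#' sum-to-zero with [membrane_rhs_reactions()].
#'
#' The components are `f = (rDEoff - rDon, rDEoff, rDEoff - rEon)`. Note the
#' first component: it is the sum of the cDD and cDT components of the flux
#' in physical variables, `f_cD = f_cDD + f_cDT = rDEoff - rDon`, as required
#' both by mass conservation at the interface and by the steady-state flux
#' condition (at a homogeneous steady state only the cDD component is
#' nonzero).
#'
#' @inheritParams reaction_rates
#' @return A named list with components `cD`, `cDD`, `cE` \[1/(um^2 s)\].
#' @export
boundary_fluxes <- function(cDT, cE, md, mde, p) {
  r <- reaction_rates(cDT, cE, md, mde, p)
  list(
    cD  = r$rDEoff - r$rDon,
    cDD = r$rDEoff,
    cE  = r$rDEoff - r$rEon
  )
}

#' Analytic Jacobians of the interface reactions and fluxes
#'
#' Partial derivatives of the membrane reaction vector
#' r = (rDon - rEon, rEon - rDEoff) and the boundary flux vector
#' f = (rDEoff - rDon, rDEoff, rDEoff - rEon) with respect to the membrane
#' densities (md, mde) and the transformed contact concentrations
#' (cD0, cDD0, cE0), evaluated at a given interface state. cDT enters the
#' kinetics as cD0 - cDD0, which is where the opposite-sign cD0/cDD0
#' columns come from.
#'
#' @param cD0,cDD0,cE0 Transformed contact concentrations \[1/um^3\].
#' @param md,mde Membrane densities \[1/um^2\].
#' @param p A [min_params()] object.
#' @return A list with matrices `Jr_m` (2 x 2), `Jr_c` (2 x 3), `Jf_m`
#'   (3 x 2), `Jf_c` (3 x 3); rows ordered as the vectors above, columns as
#'   (md, mde) and (cD0, cDD0, cE0).
#' @export
linearized_interface <- function(cD0, cDD0, cE0, md, mde, p) {
  cDT <- cD0 - cDD0
  aD <- p$kD + p$kdD * md        # d rDon / d cDT
  # elementary derivatives
  dDon  <- c(md = p$kdD * cDT, mde = 0, cD0 = aD, cDD0 = -aD, cE0 = 0)
  dEon  <- c(md = p$kdE * cE0, mde = 0, cD0 = 0, cDD0 = 0, cE0 = p$kdE * md)
  dDEof <- c(md = 0, mde = p$kde, cD0 = 0, cDD0 = 0, cE0 = 0)
  r1 <- dDon - dEon
  r2 <- dEon - dDEof
  f1 <- dDEof - dDon
  f2 <- dDEof
  f3 <- dDEof - dEon
  Jr <- rbind(r1, r2)
  Jf <- rbind(f1, f2, f3)
  list(
    Jr_m = Jr[, 1:2, drop = FALSE], Jr_c = Jr[, 3:5, drop = FALSE],
    Jf_m = Jf[, 1:2, drop = FALSE], Jf_c = Jf[, 3:5, drop = FALSE]
  )
}
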