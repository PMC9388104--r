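#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a dispersion curve
#'
#' @param x A [dispersion_curve()].
#' @param ... Unused.
#' @return A tibble with columns `q`, `re_sigma`, `im_sigma`.
#' @export
tidy.dispersion_curve <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("q", "re_sigma", "im_sigma")])
}

#' One-row summary of a dispersion curve
#'
#' @param x A [dispersion_curve()].
#' @param ... Unused.
#' @return A tibble with `unstable`, `q_star`, `q_max`, `ratio`,
#'   `oscillatory`, `re_sigma_star`, `im_sigma_star`.
#' @export
glance.dispersion_curve <- function(x, ...) {
  ss <- attr(x, "sigma_star")
  tibble::tibble(
    unstable = attr(x, "unstable"),
    q_star = as.numeric(attr(x, "q_star")),
    q_max = as.numeric(attr(x, "q_max")),
    ratio = as.numeric(attr(x, "ratio")),
    oscillatory = attr(x, "oscillatory"),
    re_sigma_star = if (is.complex(ss) || is.numeric(ss)) Re(ss) else NA_real_,
    im_sigma_star = if (is.complex(ss)) Im(ss) else NA_real_
  )
}

#' One-row summary of a reduced-dynamics trajectory
#'
#' @param x A `reduced_trajectory` from [integrate_reduced()].
#' @param ... Unused.
#' @return A tibble with final time, cell count, mass conservation error
#'   and the E:D ratio range at the final time.
#' @export
glance.reduced_trajectory <- function(x, ...) {
  last <- x[x$t == max(x$t), ]
  tibble::tibble(
    t_final = max(x$t),
    n_cells = nrow(last),
    mass_error = attr(x, "mass_error"),
    ed_ratio_min = min(last$nE / last$nD),
    ed_ratio_max = max(last$nE / last$nD)
  )
}

#' One-row summary of a regional kymograph
#'
#' @param x A [regional_kymograph()].
#' @param ... Unused.
#' @return A tibble with cell counts per pattern class and the time range.
#' @export
glance.regional_kymograph <- function(x, ...) {
  tab <- table(factor(x$class, levels = c("STABLE", "CHAOS", "SW", "TW",
                                          "FAILED")))
  out <- tibble::tibble(n_cells = nrow(x), t_min = min(x$t), t_max = max(x$t))
  for (nm in names(tab)) out[[paste0("n_", tolower(nm))]] <- as.integer(tab[[nm]])
  out
}

#' Tidy a slice-simulation mass record
#'
#' @param x A `slice_fields` object from [simulate_slice()].
#' @param ... Unused.
#' @return The mass-conservation record: tibble with `t`, `massD`,
#'   `massE` (domain-averaged totals).
#' @export
tidy.slice_fields <- function(x, ...) x$mass

#' One-row summary of a slice simulation
#'
#' @param x A `slice_fields` object.
#' @param ... Unused.
#' @return A tibble with run metadata and the relative drift of both
#'   conserved totals.
#' @export
glance.slice_fields <- function(x, ...) {
  tibble::tibble(
    H = x$H, L_y = x$L_y, t_final = max(x$t),
    n_y = length(x$y), n_z = length(x$z),
    driftD = max(abs(x$mass$massD / x$mass$massD[1] - 1)),
    driftE = max(abs(x$mass$massE / x$mass$massE[1] - 1))
  )
}
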