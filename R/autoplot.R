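#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a dispersion relation
#'
#' Real part of the leading growth rate against wavenumber (log axis),
#' with the fastest-growing mode `q*` and the right band edge `q_max`
#' marked when an unstable band exists.
#'
#' @param object A [dispersion_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dispersion_curve <- function(object, ...) {
  df <- tidy(object)
  g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$q, y = .data$re_sigma)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "wavenumber q [1/µm]",
                  y = expression(Re ~ sigma ~ "[1/s]"))
  if (isTRUE(attr(object, "unstable"))) {
    marks <- tibble::tibble(
      q = c(attr(object, "q_star"), attr(object, "q_max")),
      label = c("q*", "q[max]")
    )
    marks <- marks[is.finite(marks$q), ]
    g <- g + ggplot2::geom_vline(data = marks,
                                 ggplot2::aes(xintercept = .data$q),
                                 linetype = 2, colour = "firebrick")
  }
  g
}

#' Plot a regional pattern-type kymograph
#'
#' Space-time map of the predicted pattern class with the primary
#' `x_crit(t)` trace overlaid.
#'
#' @param object A [regional_kymograph()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.regional_kymograph <- function(object, ...) {
  df <- tibble::as_tibble(unclass(object)[c("x", "t", "class")])
  xc <- attr(object, "x_crit")
  cols <- c(STABLE = "grey85", CHAOS = "#D7191C", SW = "#FDAE61",
            TW = "#2C7BB6", FAILED = "black")
  g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$x,
                                        fill = .data$class)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = cols, name = "pattern") +
    ggplot2::labs(x = "time [s]", y = "position x [µm]")
  if (any(is.finite(xc$x_crit))) {
    g <- g + ggplot2::geom_line(
      data = xc[is.finite(xc$x_crit), ],
      ggplot2::aes(x = .data$t, y = .data$x_crit),
      inherit.aes = FALSE, colour = "green3", linewidth = 1)
  }
  g
}

#' Plot profiles of a reduced-dynamics trajectory
#'
#' Slice-total profiles along the wedge coloured by time.
#'
#' @param object A `reduced_trajectory` from [integrate_reduced()].
#' @param species `"nD"`, `"nE"` or `"ratio"` (E:D ratio).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reduced_trajectory <- function(object, species = c("nD", "nE",
                                                            "ratio"), ...) {
  species <- match.arg(species)
  df <- tibble::as_tibble(unclass(object)[c("t", "x", "nD", "nE")])
  df$value <- switch(species, nD = df$nD, nE = df$nE,
                     ratio = df$nE / df$nD)
  ylab <- switch(species, nD = "<nD> [1/µm³]",
                 nE = "<nE> [1/µm³]", ratio = "E:D ratio")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$value,
                                   colour = .data$t, group = .data$t)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_viridis_c(name = "t [s]") +
    ggplot2::labs(x = "position x [µm]", y = ylab)
}

#' Plot a membrane kymograph
#'
#' @param object A `membrane_kymograph` (from [membrane_kymograph()] or
#'   [generate_synthetic_field()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.membrane_kymograph <- function(object, ...) {
  y <- attr(object, "y"); t <- attr(object, "t")
  ycol <- rep(y, times = length(t))
  tcol <- rep(t, each = length(y))
  df <- tibble::tibble(y = ycol, t = tcol,
                       value = as.vector(unclass(object)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "membrane\ndensity") +
    ggplot2::labs(x = "time [s]", y = "y [µm]")
}

#' Plot an order-parameter snapshot with the regional stability contour
#'
#' Magnitude of the order parameter with the region where the
#' Gaussian-filtered density is below the critical density outlined.
#'
#' @param object An `at_state` from [simulate_at()].
#' @param filter_sd Gaussian filter SD (grid cells) for the overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.at_state <- function(object, filter_sd = 10, ...) {
  sm <- regional_stability_map(object, filter_sd = filter_sd)
  nx <- length(object$x); ny <- length(object$y)
  df <- tibble::tibble(x = rep(object$x, times = ny),
                       y = rep(object$y, each = nx),
                       psi = as.vector(Mod(object$psi)),
                       rho_bar = as.vector(sm$rho_bar))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$psi)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$rho_bar),
                          breaks = sm$rho_c, colour = "white",
                          linetype = 2) +
    ggplot2::scale_fill_viridis_c(name = "|ψ|") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x", y = "y")
}
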