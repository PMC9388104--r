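#' Synthetic space-time fields with known spectra
#'
#' Generates membrane-density-like fields over a (y, t) grid whose
#' space-time spectra are known analytically, as ground truth for the
#' pattern classifier and the averaging operators:
#'
#' * `"tw"`: traveling wave `offset + A sin(q y - w t)`;
#' * `"sw"`: standing wave `offset + A sin(q y) cos(w t)`;
#' * `"chaos"`: band-limited surrogate for spatiotemporal chaos -- a
#'   superposition of lateral modes in a wavenumber band around `q` whose
#'   complex amplitudes decorrelate on a time scale `tau` (discrete
#'   Ornstein-Uhlenbeck phases), giving a spectrally broad signal with RMS
#'   amplitude `A`;
#' * `"uniform"`: the constant `offset`.
#'
#' Optionally white measurement noise of standard deviation
#' `noise * A` is added.
#'
#' @param kind One of `"tw"`, `"sw"`, `"chaos"`, `"uniform"`.
#' @param y,t Grid vectors (uniform spacing).
#' @param A Amplitude.
#' @param q Central lateral wavenumber \[1/um\] (must be resolvable:
#'   `q < pi / dy`).
#' @param w Angular frequency \[1/s\].
#' @param offset Mean level added to the field.
#' @param tau Correlation time of the chaos surrogate \[s\].
#' @param bandwidth Relative wavenumber half-width of the chaos band.
#' @param noise Relative white-noise level.
#' @param seed Integer seed (chaos surrogate and noise).
#' @return A matrix (y x t) with attributes `y`, `t`, `kind`, `spec`;
#'   class `membrane_kymograph` so it can be fed to [classify_field()].
#' @export
generate_synthetic_field <- function(kind = c("tw", "sw", "chaos", "uniform"),
                                     y, t, A = 1, q = 0.5, w = 0.3,
                                     offset = 0, tau = NULL, bandwidth = 0.3,
                                     noise = 0, seed = 1L) {
  kind <- match.arg(kind)
  dy <- y[2] - y[1]
  if (kind != "uniform" && q >= pi / dy) {
    stop(sprintf("wavenumber q = %g violates the lateral Nyquist limit %g",
                 q, pi / dy))
  }
  ny <- length(y); nt <- length(t)
  set.seed(seed)
  F <- switch(kind,
    uniform = matrix(offset, ny, nt),
    tw = offset + A * sin(outer(q * y, w * t, "-")),
    sw = offset + A * outer(sin(q * y), cos(w * t)),
    chaos = {
      if (is.null(tau)) tau <- 4 * pi / w   # ~2 dominant periods
      ks <- 2 * pi * seq_len(floor(ny / 2)) / (ny * dy)
      band <- which(abs(ks - q) <= bandwidth * q)
      if (!length(band)) band <- which.min(abs(ks - q))
      nb <- length(band)
      dtau <- t[2] - t[1]
      rho <- exp(-dtau / tau)
      # each mode oscillates near the carrier frequency (jittered, random
      # sign) while its complex amplitude decorrelates -- a broad spectral
      # blob around (q, w) like oscillatory chemical turbulence
      wk <- w * (1 + bandwidth * stats::runif(nb, -1, 1)) *
        sample(c(-1, 1), nb, replace = TRUE)
      rot <- exp(-1i * wk * dtau)
      amp <- matrix(0 + 0i, nb, nt)
      amp[, 1] <- stats::rnorm(nb) + 1i * stats::rnorm(nb)
      for (j in 2:nt) {
        amp[, j] <- rot * (rho * amp[, j - 1] +
                             sqrt(1 - rho^2) *
                               (stats::rnorm(nb) + 1i * stats::rnorm(nb)))
      }
      phase <- exp(1i * outer(ks[band], y))   # modes x y
      raw <- Re(t(phase) %*% amp)             # y x t
      offset + A * raw / sqrt(mean(raw^2))
    })
  if (noise > 0) F <- F + noise * A * matrix(stats::rnorm(ny * nt), ny, nt)
  structure(F, class = c("membrane_kymograph", "matrix", "array"),
            y = y, t = t, kind = kind,
            spec = list(A = A, q = q, w = w, offset = offset,
                        noise = noise, seed = seed))
}
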