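#' Rule-based space-time pattern classifier
#'
#' Classifies a membrane kymograph (density over y and t) as traveling
#' waves, standing waves, spatiotemporal chaos, or no pattern. Because
#' fully developed wave patterns organize into domains (left- and
#' right-moving waves separated by persistent sources and sinks), the
#' analysis is local: the kymograph is cut into overlapping lateral
#' windows a few dominant wavelengths wide, and each window is scored by
#' its 2D space-time power spectrum `P(q, w)`:
#'
#' * window directionality `D = (P+ - P-) / (P+ + P-)`, with `P+`/`P-`
#'   the power at `q * w` of either sign on the dominant spectral ridge --
#'   a traveling wave puts its power on one diagonal (`|D| -> 1`), a
#'   standing wave splits it evenly (`D -> 0`);
#' * window spectral entropy (normalized), high for spectrally broad,
#'   disordered dynamics.
#'
#' The field is `NONE` if its fluctuating (AC) part is negligible;
#' `CHAOS` if the median window entropy exceeds a threshold; otherwise
#' `TW` if the median window `|D|` exceeds a threshold, else `SW`.
#'
#' @param kymo Matrix (y x t) of membrane density, e.g. from
#'   [membrane_kymograph()] or [generate_synthetic_field()].
#' @param y,t Grid vectors (uniform); defaults taken from attributes if
#'   present.
#' @param thresholds List: `ac_min` (minimum RMS fluctuation relative to
#'   the mean, default 1e-3), `entropy_chaos` (median window entropy above
#'   which the field is chaotic, default 0.45), `D_tw` (median window
#'   directionality above which waves are traveling, default 0.5),
#'   `ridge_frac` (fraction of the window peak power defining its ridge,
#'   default 0.05), `win_wavelengths` (window width in dominant
#'   wavelengths, default 4).
#' @param min_periods Minimum number of dominant oscillation periods the
#'   series must span (default 8).
#' @return A list of class `pattern_classification`: `class` (factor in
#'   NONE/CHAOS/SW/TW), `directionality` (median window `|D|`), `entropy`
#'   (median window entropy), `q_peak`, `w_peak` (global), `n_periods`,
#'   `ac_rms`, `windows` (tibble of per-window scores).
#' @export
classify_field <- function(kymo, y = attr(kymo, "y"), t = attr(kymo, "t"),
                           thresholds = list(), min_periods = 8) {
  thr <- utils::modifyList(list(ac_min = 1e-3, entropy_chaos = 0.45,
                                D_tw = 0.5, ridge_frac = 0.05,
                                win_wavelengths = 4), thresholds)
  kymo <- unclass(kymo)
  ny <- nrow(kymo); nt <- ncol(kymo)
  stopifnot(length(y) == ny, length(t) == nt)
  dy <- y[2] - y[1]; dtau <- t[2] - t[1]

  mu <- mean(kymo)
  ac <- kymo - rowMeans(kymo)          # remove static lateral profile
  ac_rms <- sqrt(mean(ac^2))
  lv <- c("NONE", "CHAOS", "SW", "TW")
  none <- function() {
    structure(list(class = factor("NONE", levels = lv),
                   directionality = NA_real_, entropy = NA_real_,
                   q_peak = NA_real_, w_peak = NA_real_,
                   n_periods = NA_real_, ac_rms = ac_rms,
                   windows = NULL),
              class = "pattern_classification")
  }
  if (!is.finite(ac_rms) || ac_rms < thr$ac_min * max(abs(mu), 1e-300)) {
    return(none())
  }

  # global dominant mode locates the wavelength and checks the duration
  gs <- spectrum_scores(ac, dy, dtau, thr$ridge_frac)
  if (is.null(gs)) return(none())
  n_periods <- diff(range(t)) * gs$w0 / (2 * pi)
  if (n_periods < min_periods) {
    stop(sprintf(paste("time series too short: %.1f dominant periods",
                       "sampled, need >= %g"), n_periods, min_periods))
  }

  # overlapping lateral windows, a few dominant wavelengths wide
  win_len <- max(8L, min(ny, ceiling(thr$win_wavelengths * 2 * pi /
                                       (gs$q0 * dy))))
  starts <- unique(pmin(seq(1L, ny - win_len + 1L,
                            by = max(1L, win_len %/% 2L)),
                        ny - win_len + 1L))
  wins <- lapply(starts, function(s) {
    ws <- spectrum_scores(ac[s:(s + win_len - 1L), , drop = FALSE],
                          dy, dtau, thr$ridge_frac)
    if (is.null(ws)) return(NULL)
    tibble::tibble(y_start = y[s], D = ws$D, entropy = ws$entropy,
                   q_peak = ws$q0, w_peak = ws$w0)
  })
  wins <- dplyr::bind_rows(wins[!vapply(wins, is.null, logical(1))])
  if (nrow(wins) == 0) return(none())

  med_D <- stats::median(abs(wins$D))
  med_H <- stats::median(wins$entropy)
  cls <- if (med_H > thr$entropy_chaos) "CHAOS"
    else if (med_D > thr$D_tw) "TW"
    else "SW"
  structure(list(class = factor(cls, levels = lv), directionality = med_D,
                 entropy = med_H, q_peak = gs$q0, w_peak = gs$w0,
                 n_periods = n_periods, ac_rms = ac_rms, windows = wins),
            class = "pattern_classification")
}

# spectral scores of one (possibly windowed) AC field: dominant (|q|, |w|),
# ridge directionality and normalized spectral entropy
spectrum_scores <- function(ac, dy, dtau, ridge_frac) {
  ny <- nrow(ac); nt <- ncol(ac)
  # Hann taper in y reduces window-edge leakage
  taper <- 0.5 - 0.5 * cos(2 * pi * (seq_len(ny) - 0.5) / ny)
  P <- Mod(stats::fft(ac * taper))^2
  qs <- 2 * pi * (seq_len(ny) - 1) / (ny * dy)
  qs[qs > pi / dy] <- qs[qs > pi / dy] - 2 * pi / dy
  ws <- 2 * pi * (seq_len(nt) - 1) / (nt * dtau)
  ws[ws > pi / dtau] <- ws[ws > pi / dtau] - 2 * pi / dtau
  Q <- matrix(qs, ny, nt)
  W <- matrix(ws, ny, nt, byrow = TRUE)
  sel <- Q != 0 & W != 0
  Psel <- P * sel
  tot <- sum(Psel)
  if (tot <= 0) return(NULL)
  pk <- arrayInd(which.max(Psel), dim(P))
  q0 <- abs(Q[pk]); w0 <- abs(W[pk])
  pn <- Psel[sel] / tot
  pn <- pn[pn > 0]
  entropy <- -sum(pn * log(pn)) / log(length(pn))
  ridge <- sel & Psel >= ridge_frac * Psel[pk[1], pk[2]]
  Pp <- sum(Psel[ridge & (Q * W > 0)])
  Pm <- sum(Psel[ridge & (Q * W < 0)])
  list(q0 = q0, w0 = w0, D = (Pp - Pm) / (Pp + Pm), entropy = entropy)
}

#' @export
print.pattern_classification <- function(x, ...) {
  cat(sprintf(paste0("pattern: %s (median |D| = %.3f, median entropy =",
                     " %.3f, q = %.3g, w = %.3g)\n"),
              as.character(x$class), x$directionality, x$entropy,
              x$q_peak, x$w_peak))
  invisible(x)
}
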