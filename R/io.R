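#' Read and write Min model parameters
#'
#' Parameters are serialized as a flat key-value YAML record with exactly
#' the nine fields of [min_params()]; unknown or missing keys raise an
#' error naming the offender.
#'
#' @param path File path.
#' @param p A [min_params()] object (for writing).
#' @return `read_min_params` returns a [min_params()] object;
#'   `write_min_params` returns `path` invisibly.
#' @export
read_min_params <- function(path) {
  raw <- yaml::read_yaml(path)
  wanted <- c("Dc", "Dm", "kD", "kdD", "kdE", "kde", "lam",
              "nD_bar", "nE_bar")
  unknown <- setdiff(names(raw), wanted)
  if (length(unknown)) {
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "))
  }
  missing <- setdiff(wanted, names(raw))
  if (length(missing)) {
    stop("missing parameter key(s): ", paste(missing, collapse = ", "))
  }
  do.call(min_params, lapply(raw[wanted], as.numeric))
}

#' @rdname read_min_params
#' @export
write_min_params <- function(p, path) {
  stopifnot(inherits(p, "min_params"))
  yaml::write_yaml(lapply(unclass(p), as.numeric), path)
  invisible(path)
}

#' Lossless CSV round trip for numeric tables
#'
#' Thin wrappers over base CSV I/O that format doubles with 17 significant
#' digits, so a write-read round trip reproduces every value bit for bit.
#'
#' @param df A data frame.
#' @param path File path.
#' @return `read_table_csv` returns a tibble; `write_table_csv` returns
#'   `path` invisibly.
#' @export
write_table_csv <- function(df, path) {
  df2 <- as.data.frame(lapply(df, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else col
  }), check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df2, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
}

#' Field (matrix) I/O in long CSV format
#'
#' Writes a space-time field sampled on a rectilinear grid as a long CSV
#' with columns `y`, `t`, `value` (losslessly, see [write_table_csv()]),
#' and reads it back into a matrix with grid attributes.
#'
#' @param field Matrix (y x t) with optional `y`, `t` attributes.
#' @param y,t Grid vectors (default from attributes).
#' @param path File path.
#' @return `read_field_csv` returns the matrix with `y` and `t`
#'   attributes.
#' @export
write_field_csv <- function(field, path, y = attr(field, "y"),
                            t = attr(field, "t")) {
  stopifnot(nrow(field) == length(y), ncol(field) == length(t))
  ycol <- rep(y, times = length(t))
  tcol <- rep(t, each = length(y))
  df <- tibble::tibble(y = ycol, t = tcol,
                       value = as.vector(unclass(field)))
  write_table_csv(df, path)
}

#' @rdname write_field_csv
#' @export
read_field_csv <- function(path) {
  df <- read_table_csv(path)
  y <- sort(unique(df$y)); t <- sort(unique(df$t))
  m <- matrix(NA_real_, length(y), length(t))
  m[cbind(match(df$y, y), match(df$t, t))] <- df$value
  structure(m, y = y, t = t)
}

#' Load and validate a run configuration
#'
#' Structured YAML configuration with four blocks -- `params` (path to a
#' parameter file or an inline parameter record), `geometry` (`L`, `H0`,
#' `H1` for a wedge or `H`, `L_y` for a slice), `run` (`T`, `seed`,
#' `sample_dt`) and `numerics` (`n_cells`, `n_y`, `n_z`, `dt`, `kappa`,
#' `r_TW`, classifier thresholds) -- with schema validation: unknown keys
#' anywhere are rejected by name, and every numeric knob is range-checked.
#'
#' @param path Path to the YAML configuration.
#' @return A named list with validated blocks (class `run_config`).
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  blocks <- c("params", "geometry", "run", "numerics")
  unknown <- setdiff(names(raw), blocks)
  if (length(unknown)) {
    stop("unknown configuration block(s): ", paste(unknown, collapse = ", "))
  }
  schema <- list(
    geometry = list(L = c(0, Inf), H0 = c(0, Inf), H1 = c(0, Inf),
                    H = c(0, Inf), L_y = c(0, Inf)),
    run = list(T = c(0, Inf), seed = c(-2^31, 2^31), sample_dt = c(0, Inf)),
    numerics = list(n_cells = c(2, 1e5), n_y = c(4, 1e5), n_z = c(4, 1e4),
                    dt = c(0, 10), kappa = c(0, Inf), r_TW = c(2, 10),
                    entropy_chaos = c(0, 1), D_tw = c(0, 1))
  )
  for (blk in intersect(names(schema), names(raw))) {
    vals <- raw[[blk]]
    unknown <- setdiff(names(vals), names(schema[[blk]]))
    if (length(unknown)) {
      stop(sprintf("unknown key(s) in block '%s': %s", blk,
                   paste(unknown, collapse = ", ")))
    }
    for (key in names(vals)) {
      rng <- schema[[blk]][[key]]
      v <- vals[[key]]
      if (!is.numeric(v) || length(v) != 1 || v <= rng[1] || v > rng[2]) {
        stop(sprintf("configuration value %s.%s = %s outside (%g, %g]",
                     blk, key, format(v), rng[1], rng[2]))
      }
    }
  }
  if (!is.null(raw$params)) {
    raw$params <- if (is.character(raw$params)) read_min_params(raw$params)
      else do.call(min_params, lapply(raw$params, as.numeric))
  }
  structure(raw, class = "run_config")
}
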