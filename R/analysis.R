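# Post-processing: normalization by the stapes drive, local smoothing,
# tuning-map extraction, Greenwood frequency-place comparison, and
# healthy-vs-implanted residual-hearing deltas.

#' Normalize a response by the stapes displacement
#'
#' @param resp A `bm_response` from [solve_harmonic()].
#' @return Matrix of `|u(x)| / |u_s(f)|` (nodes x frequencies),
#'   dimensionless, with frequency column names.
#' @export
normalize_response <- function(resp) {
  stopifnot(inherits(resp, "bm_response"))
  if (any(resp$us == 0)) stop("stapes displacement is zero; cannot normalize")
  sweep(abs(resp$u), 2, resp$us, "/")
}

#' Smooth a profile with a centered moving average
#'
#' Local filter across a fixed spatial window (default 0.2 mm), implemented
#' as a centered moving average with reflective edge handling. Constant
#' profiles pass through unchanged; the output lives on the input grid.
#'
#' @param values Numeric vector on a uniform grid.
#' @param x Grid positions, mm (uniform spacing).
#' @param window_mm Full window width, mm; must be at least the grid step.
#' @return Smoothed numeric vector of the same length.
#' @export
smooth_profile <- function(values, x, window_mm = 0.2) {
  n <- length(values)
  stopifnot(length(x) == n, n >= 2)
  dx <- x[2] - x[1]
  if (window_mm < dx) stop("window_mm must be >= the grid step dx")
  k <- max(1L, floor(window_mm / (2 * dx)))
  # reflective padding, then uniform kernel of width 2k+1
  padded <- c(values[(k + 1):2], values, values[(n - 1):(n - k)])
  kern <- rep(1 / (2 * k + 1), 2 * k + 1)
  as.numeric(stats::filter(padded, kern, sides = 2))[(k + 1):(k + n)]
}

#' Locate the profile maximum
#'
#' Global maximum of a (smoothed) profile; ties are broken toward the base
#' (smallest x). An all-zero or non-finite profile is flagged rather than
#' located.
#'
#' @param values Numeric profile.
#' @param x Grid positions, mm.
#' @return List with `x_max`, `peak` and logical `flagged`.
#' @export
find_peak <- function(values, x) {
  stopifnot(length(values) == length(x), length(x) >= 1)
  if (!any(is.finite(values)) || all(values == 0)) {
    return(list(x_max = NA_real_, peak = NA_real_, flagged = TRUE))
  }
  i <- which.max(values)  # which.max returns the first (most basal) maximum
  list(x_max = x[i], peak = values[i], flagged = FALSE)
}

#' Extract the tuning map from a response
#'
#' Per-frequency peak location and normalized peak magnitude of the smoothed,
#' stapes-normalized displacement profile.
#'
#' @param resp A `bm_response`.
#' @param window_mm Smoothing window forwarded to [smooth_profile()].
#' @return An object of class `tuning_result`: a data.frame with columns
#'   `frequency_Hz`, `x_max_mm`, `normalized_peak`, `flagged`, carrying the
#'   grid and run metadata as attributes.
#' @export
extract_tuning <- function(resp, window_mm = 0.2) {
  stopifnot(inherits(resp, "bm_response"))
  nm <- normalize_response(resp)
  rows <- lapply(seq_along(resp$frequencies_Hz), function(k) {
    sm <- smooth_profile(nm[, k], resp$x, window_mm)
    pk <- find_peak(sm, resp$x)
    data.frame(frequency_Hz = resp$frequencies_Hz[k],
               x_max_mm = pk$x_max, normalized_peak = pk$peak,
               flagged = pk$flagged)
  })
  out <- do.call(rbind, rows)
  attr(out, "L") <- max(resp$x)
  attr(out, "dx_mm") <- resp$x[2] - resp$x[1]
  attr(out, "angle_deg") <- resp$angle_deg
  attr(out, "window_mm") <- window_mm
  class(out) <- c("tuning_result", "data.frame")
  out
}

#' Greenwood frequency-place map
#'
#' The Greenwood (1990) function `F(xt) = A * (10^(a * xt) - k)` with `xt`
#' the proportional distance from the apex. Shipped presets are the
#' chinchilla constants (default) and the human constants; all three
#' constants can be overridden. These are external-literature benchmark
#' values, not quantities of this model.
#'
#' @param species `"chinchilla"` or `"human"`.
#' @param A,a,k Optional overrides of the map constants.
#' @return An object of class `greenwood_map`.
#' @export
greenwood_map <- function(species = c("chinchilla", "human"),
                          A = NULL, a = NULL, k = NULL) {
  species <- match.arg(species)
  preset <- switch(species,
                   chinchilla = list(A = 163.5, a = 2.1, k = 0.85),
                   human = list(A = 165.4, a = 2.1, k = 0.88))
  m <- list(A = if (is.null(A)) preset$A else A,
            a = if (is.null(a)) preset$a else a,
            k = if (is.null(k)) preset$k else k,
            species = species)
  if (m$A <= 0 || m$a <= 0) stop("greenwood map requires A > 0 and a > 0")
  structure(m, class = "greenwood_map")
}

#' Predicted peak position for a frequency under a Greenwood map
#'
#' Inverts the map: `xt = log10(F/A + k) / a`, position from the base
#' `x = L * (1 - xt)`. Frequencies outside the invertible range of the map
#' (xt outside `[0, 1]`) return `NA`.
#'
#' @param map A [greenwood_map()].
#' @param frequency_Hz Frequency or frequencies, Hz.
#' @param L BM length, mm.
#' @return Predicted position(s) from the base, mm (`NA` where out of range).
#' @export
greenwood_position <- function(map, frequency_Hz, L) {
  stopifnot(inherits(map, "greenwood_map"))
  xt <- log10(frequency_Hz / map$A + map$k) / map$a
  x <- L * (1 - xt)
  x[xt < 0 | xt > 1] <- NA_real_
  x
}

#' Compare a tuning map against the Greenwood prediction
#'
#' @param tuning A [extract_tuning()] result.
#' @param map A [greenwood_map()].
#' @return The tuning data.frame with added columns `greenwood_x_mm` and
#'   `error_mm` (signed, model minus prediction), and attribute `rms_mm`
#'   (root-mean-square location error over the in-range frequencies).
#' @export
compare_greenwood <- function(tuning, map = greenwood_map()) {
  stopifnot(inherits(tuning, "tuning_result"))
  L <- attr(tuning, "L")
  gx <- greenwood_position(map, tuning$frequency_Hz, L)
  out <- tuning
  out$greenwood_x_mm <- gx
  out$error_mm <- out$x_max_mm - gx
  ok <- is.finite(out$error_mm)
  attr(out, "rms_mm") <- if (any(ok)) sqrt(mean(out$error_mm[ok]^2)) else NA_real_
  out
}

#' Residual-hearing deltas between two runs
#'
#' Per-frequency peak-location shift and normalized-peak magnitude change
#' between identically configured runs that differ only in the electrode.
#' Positive `dx_mm` means the implanted peak moved apically; `ddB` is
#' `20 log10(implanted / healthy)` of the normalized peak.
#'
#' @param healthy,implanted [extract_tuning()] results on the same grid,
#'   frequencies and smoothing window.
#' @return An object of class `residual_delta`: data.frame with columns
#'   `angle_deg`, `frequency_Hz`, `dx_mm`, `ddB`, with attributes
#'   `max_abs_dx_mm` and `max_abs_ddB`.
#' @export
residual_hearing_delta <- function(healthy, implanted) {
  stopifnot(inherits(healthy, "tuning_result"),
            inherits(implanted, "tuning_result"))
  for (field in c("L", "dx_mm", "window_mm")) {
    if (!isTRUE(all.equal(attr(healthy, field), attr(implanted, field)))) {
      stop("runs differ in ", field, "; deltas require identical configuration")
    }
  }
  if (!identical(healthy$frequency_Hz, implanted$frequency_Hz)) {
    stop("runs differ in frequencies_Hz; deltas require identical stimulus")
  }
  out <- data.frame(angle_deg = attr(implanted, "angle_deg"),
                    frequency_Hz = healthy$frequency_Hz,
                    dx_mm = implanted$x_max_mm - healthy$x_max_mm,
                    ddB = 20 * log10(implanted$normalized_peak /
                                       healthy$normalized_peak))
  attr(out, "max_abs_dx_mm") <- max(abs(out$dx_mm))
  attr(out, "max_abs_ddB") <- max(abs(out$ddB))
  class(out) <- c("residual_delta", "data.frame")
  out
}

#' Export a tuning table to CSV
#'
#' Columns: `frequency_Hz, x_max_mm, normalized_peak, greenwood_x_mm,
#' error_mm` (the last two only if [compare_greenwood()] was applied).
#'
#' @param tuning A `tuning_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tuning_csv <- function(tuning, path) {
  stopifnot(inherits(tuning, "tuning_result"))
  utils::write.csv(as.data.frame(tuning), path, row.names = FALSE)
  invisible(path)
}
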