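# Parametric cochlear geometry: spiral centerline, basilar-membrane (BM)
# dimension profiles, duct cross-sections, and the discretization grid.
# This is the synthetic stand-in for a scan-derived mesh: every profile is a
# simple documented parametric law, scaled so the BM midline hits the target
# length exactly.

#' Spiral centerline specification
#'
#' Describes the coiled centerline of the cochlea in the mid-modiolar plane.
#' Two forms are supported: a logarithmic spiral `r(theta) = r0 *
#' exp(-taper_rate * theta)` (the default, matching the near-constant pitch
#' angle of mammalian cochlear coiling) and an Archimedean spiral
#' `r(theta) = r0 * (1 - taper_rate * theta)`, with `theta` in radians
#' measured from the basal end.
#'
#' @param total_angle_deg Total coil angle in degrees. Must be at least 900
#'   so the deepest electrode insertion fits on the spiral. Default 1080
#'   (three turns).
#' @param basal_radius_mm Centerline radius at the base, mm. Default 2.
#' @param taper_rate Per-radian fractional shrink of the spiral radius
#'   (dimensionless). Default 0.12.
#' @param form `"logarithmic"` or `"archimedean"`.
#' @return An object of class `spiral_spec`.
#' @examples
#' sp <- spiral_spec()
#' angle_to_arclength(sp, 360)
#' @export
spiral_spec <- function(total_angle_deg = 1080, basal_radius_mm = 2,
                        taper_rate = 0.12, form = c("logarithmic", "archimedean")) {
  form <- match.arg(form)
  if (!is.numeric(total_angle_deg) || length(total_angle_deg) != 1 ||
      total_angle_deg < 900) {
    stop("total_angle_deg must be a single number >= 900 (deepest electrode is 900 degrees)")
  }
  if (!is.numeric(basal_radius_mm) || basal_radius_mm <= 0) {
    stop("basal_radius_mm must be positive")
  }
  if (!is.numeric(taper_rate) || taper_rate < 0) {
    stop("taper_rate must be non-negative")
  }
  theta_tot <- total_angle_deg * pi / 180
  if (form == "archimedean" && taper_rate * theta_tot >= 1) {
    stop("taper_rate too large: Archimedean spiral radius reaches zero before total_angle_deg")
  }
  structure(list(total_angle_deg = total_angle_deg,
                 basal_radius_mm = basal_radius_mm,
                 taper_rate = taper_rate, form = form),
            class = "spiral_spec")
}

#' Discretization grid specification
#'
#' @param dx_mm Spatial step along the BM midline, mm. The default (0.0025 mm)
#'   resolves the shortest traveling-wave wavelength that arises near the
#'   response peak under the default graded damping law; see the methods
#'   vignette for the resolution argument.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(dx_mm = 0.0025) {
  if (!is.numeric(dx_mm) || length(dx_mm) != 1 || dx_mm <= 0 || dx_mm > 0.5) {
    stop("dx_mm must be a single value in (0, 0.5]")
  }
  structure(list(dx_mm = dx_mm), class = "grid_spec")
}

# centerline radius (mm) at angle theta (radians)
spiral_radius <- function(spiral, theta) {
  switch(spiral$form,
         logarithmic = spiral$basal_radius_mm * exp(-spiral$taper_rate * theta),
         archimedean = spiral$basal_radius_mm * (1 - spiral$taper_rate * theta))
}

# |d(position)/d(theta)| (mm per radian) at angle theta (radians)
spiral_speed <- function(spiral, theta) {
  r <- spiral_radius(spiral, theta)
  switch(spiral$form,
         logarithmic = r * sqrt(1 + spiral$taper_rate^2),
         archimedean = sqrt(r^2 + (spiral$basal_radius_mm * spiral$taper_rate)^2))
}

#' Arc length along the spiral centerline up to a given angle
#'
#' Closed-form arc length of the centerline from the basal end (`theta = 0`)
#' to `theta_deg`, strictly increasing in the angle.
#'
#' @param spiral A [spiral_spec()].
#' @param theta_deg Insertion angle(s), degrees, in `[0, total_angle_deg]`.
#' @return Arc length(s) in mm (un-scaled spiral units; [build_geometry()]
#'   applies the global scale factor).
#' @export
angle_to_arclength <- function(spiral, theta_deg) {
  stopifnot(inherits(spiral, "spiral_spec"))
  if (any(theta_deg < 0 | theta_deg > spiral$total_angle_deg)) {
    stop("theta_deg out of range [0, ", spiral$total_angle_deg, "]")
  }
  th <- theta_deg * pi / 180
  b <- spiral$taper_rate
  r0 <- spiral$basal_radius_mm
  if (spiral$form == "logarithmic") {
    if (b == 0) return(r0 * th)
    r0 * sqrt(1 + b^2) * (1 - exp(-b * th)) / b
  } else {
    if (b == 0) return(r0 * th)
    # ds = sqrt(r^2 + c^2) dtheta with r = r0 (1 - b theta), c = r0 b
    cc <- r0 * b
    F <- function(r) (r * sqrt(r^2 + cc^2) + cc^2 * asinh(r / cc)) / 2
    r_th <- r0 * (1 - b * th)
    (F(r0) - F(r_th)) / cc
  }
}

#' Angle at a given arc length along the spiral centerline
#'
#' Inverse of [angle_to_arclength()]. Analytic for the logarithmic form,
#' bisection-free root solve for the Archimedean form.
#'
#' @param spiral A [spiral_spec()].
#' @param s_mm Arc length(s) from the base, mm (un-scaled spiral units).
#' @return Angle(s) in degrees.
#' @export
arclength_to_angle <- function(spiral, s_mm) {
  stopifnot(inherits(spiral, "spiral_spec"))
  s_tot <- angle_to_arclength(spiral, spiral$total_angle_deg)
  if (any(s_mm < 0 | s_mm > s_tot * (1 + 1e-12))) {
    stop("s_mm out of range [0, ", format(s_tot), "]")
  }
  s_mm <- pmin(s_mm, s_tot)
  b <- spiral$taper_rate
  r0 <- spiral$basal_radius_mm
  if (spiral$form == "logarithmic") {
    if (b == 0) return(s_mm / r0 * 180 / pi)
    th <- -log(1 - s_mm * b / (r0 * sqrt(1 + b^2))) / b
    return(th * 180 / pi)
  }
  vapply(s_mm, function(s) {
    if (s == 0) return(0)
    f <- function(td) angle_to_arclength(spiral, td) - s
    stats::uniroot(f, c(0, spiral$total_angle_deg), tol = 1e-10)$root
  }, numeric(1))
}

#' Build the parametric cochlear geometry
#'
#' Constructs the discretized two-duct uncoiled cochlea: an `x` grid along
#' the BM midline from base (`x = 0`) to apex (`x = L`), thickness/width/area
#' profiles, and the monotone map between arc length and insertion angle on
#' the spiral centerline. The spiral is scaled by a single factor so the BM
#' midline has exactly the requested length; `x` is arc length along the
#' scaled centerline.
#'
#' Dimension profiles are linear tapers between configurable endpoints. The
#' thickness endpoints default to the measured chinchilla values (16.5 um at
#' the base, 5 um at the apex); width and duct-area endpoints are
#' literature-typical defaults, not measurements.
#'
#' @param length_mm Target BM midline length, mm. Default 18.3, the average
#'   chinchilla value.
#' @param spiral A [spiral_spec()].
#' @param grid A [grid_spec()].
#' @param thickness_base_um,thickness_apex_um BM thickness endpoints, um.
#' @param width_base_mm,width_apex_mm BM width endpoints, mm.
#' @param area_sv_base_mm2,area_sv_apex_mm2 Effective cross-section of the
#'   upper duct (scala vestibuli + media), mm^2, at base and apex.
#' @param area_st_base_mm2,area_st_apex_mm2 Scala-tympani cross-section,
#'   mm^2, at base and apex.
#' @param thickness_profile `"linear"` (default) or `"exponential"`; both are
#'   monotone interpolants pinned to the two thickness endpoints.
#' @return An object of class `cochlear_geometry` with fields `L`, `x`
#'   (grid, mm), `t_um`, `w_mm`, `A_sv_mm2`, `A_st_mm2`, `angle_deg`
#'   (insertion angle at each node), `spiral`, `grid`, `scale` (spiral scale
#'   factor) and the endpoint parameters.
#' @examples
#' geom <- build_geometry(grid = grid_spec(0.05))
#' geom$L
#' range(geom$t_um)
#' @export
build_geometry <- function(length_mm = 18.3,
                           spiral = spiral_spec(),
                           grid = grid_spec(),
                           thickness_base_um = 16.5, thickness_apex_um = 5,
                           width_base_mm = 0.125, width_apex_mm = 0.25,
                           area_sv_base_mm2 = 0.8, area_sv_apex_mm2 = 0.3,
                           area_st_base_mm2 = 0.8, area_st_apex_mm2 = 0.3,
                           thickness_profile = c("linear", "exponential")) {
  thickness_profile <- match.arg(thickness_profile)
  stopifnot(inherits(spiral, "spiral_spec"), inherits(grid, "grid_spec"))
  dims <- c(length_mm = length_mm,
            thickness_base_um = thickness_base_um,
            thickness_apex_um = thickness_apex_um,
            width_base_mm = width_base_mm, width_apex_mm = width_apex_mm,
            area_sv_base_mm2 = area_sv_base_mm2,
            area_sv_apex_mm2 = area_sv_apex_mm2,
            area_st_base_mm2 = area_st_base_mm2,
            area_st_apex_mm2 = area_st_apex_mm2)
  bad <- names(dims)[!is.finite(dims) | dims <= 0]
  if (length(bad)) stop("non-positive geometry dimension(s): ",
                        paste(bad, collapse = ", "))
  if (length_mm / grid$dx_mm < 50) {
    stop("grid too coarse: length_mm/dx_mm must be >= 50")
  }

  n <- ceiling(length_mm / grid$dx_mm)
  x <- seq(0, length_mm, length.out = n + 1)

  s_tot <- angle_to_arclength(spiral, spiral$total_angle_deg)
  scale <- length_mm / s_tot
  angle_deg <- arclength_to_angle(spiral, x / scale)

  interp <- function(v0, v1) v0 + (v1 - v0) * x / length_mm
  t_um <- if (thickness_profile == "linear") {
    interp(thickness_base_um, thickness_apex_um)
  } else {
    thickness_base_um *
      (thickness_apex_um / thickness_base_um)^(x / length_mm)
  }

  structure(list(L = length_mm, x = x,
                 t_um = t_um,
                 w_mm = interp(width_base_mm, width_apex_mm),
                 A_sv_mm2 = interp(area_sv_base_mm2, area_sv_apex_mm2),
                 A_st_mm2 = interp(area_st_base_mm2, area_st_apex_mm2),
                 angle_deg = angle_deg,
                 spiral = spiral, grid = grid, scale = scale,
                 thickness_profile = thickness_profile,
                 endpoints = as.list(dims)),
            class = "cochlear_geometry")
}

#' BM thickness at an arbitrary position
#'
#' Continuous, monotone non-increasing interpolation between the two
#' configured thickness endpoints (linear in arc length by default).
#'
#' @param geom A [build_geometry()] result.
#' @param x_mm Position(s) from the base, mm, in `[0, L]`.
#' @return Thickness in um.
#' @export
thickness_at <- function(geom, x_mm) {
  stopifnot(inherits(geom, "cochlear_geometry"))
  if (any(x_mm < 0 | x_mm > geom$L)) stop("x_mm out of range [0, ", geom$L, "]")
  e <- geom$endpoints
  if (geom$thickness_profile == "linear") {
    e$thickness_base_um +
      (e$thickness_apex_um - e$thickness_base_um) * x_mm / geom$L
  } else {
    e$thickness_base_um *
      (e$thickness_apex_um / e$thickness_base_um)^(x_mm / geom$L)
  }
}

#' @export
print.cochlear_geometry <- function(x, ...) {
  cat("cochlear_geometry:\n")
  cat(sprintf("  BM midline length  %g mm (%d nodes, dx = %g mm)\n",
              x$L, length(x$x), x$grid$dx_mm))
  cat(sprintf("  thickness          %g -> %g um (%s)\n",
              x$t_um[1], x$t_um[length(x$t_um)], x$thickness_profile))
  cat(sprintf("  width              %g -> %g mm\n",
              x$w_mm[1], x$w_mm[length(x$w_mm)]))
  cat(sprintf("  spiral             %s, %g deg total, scale %.4f\n",
              x$spiral$form, x$spiral$total_angle_deg, x$scale))
  invisible(x)
}

#' Export geometry profiles to CSV
#'
#' One row per grid node: `x_mm, thickness_um, width_mm, A_sv_mm2, A_st_mm2,
#' angle_deg`.
#'
#' @param geom A `cochlear_geometry`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_geometry_csv <- function(geom, path) {
  stopifnot(inherits(geom, "cochlear_geometry"))
  df <- data.frame(x_mm = geom$x, thickness_um = geom$t_um,
                   width_mm = geom$w_mm, A_sv_mm2 = geom$A_sv_mm2,
                   A_st_mm2 = geom$A_st_mm2, angle_deg = geom$angle_deg)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export the spiral centerline as a legacy VTK polyline
#'
#' Writes an ASCII legacy-format VTK file with the 3-D centerline points
#' (planar spiral, z = 0) and per-point data arrays for thickness, width,
#' duct areas and insertion angle.
#'
#' @param geom A `cochlear_geometry`.
#' @param path Output file path (conventionally `.vtk`).
#' @return `path`, invisibly.
#' @export
write_geometry_vtk <- function(geom, path) {
  stopifnot(inherits(geom, "cochlear_geometry"))
  th <- geom$angle_deg * pi / 180
  r <- spiral_radius(geom$spiral, th) * geom$scale
  pts <- cbind(r * cos(th), r * sin(th), 0)
  n <- nrow(pts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "cochlear centerline", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", n)), con)
  utils::write.table(format(pts, digits = 10, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("LINES 1 %d", n + 1), con)
  writeLines(paste(c(n, seq_len(n) - 1L), collapse = " "), con)
  writeLines(sprintf("POINT_DATA %d", n), con)
  arrays <- list(thickness_um = geom$t_um, width_mm = geom$w_mm,
                 A_sv_mm2 = geom$A_sv_mm2, A_st_mm2 = geom$A_st_mm2,
                 angle_deg = geom$angle_deg)
  for (nm in names(arrays)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"),
               con)
    writeLines(format(arrays[[nm]], digits = 10, trim = TRUE), con)
  }
  invisible(path)
}
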