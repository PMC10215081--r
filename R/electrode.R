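# Cochlear-implant electrode as a tapered body occupying the scala tympani up
# to a configurable insertion angle, reduced to per-position occlusion and
# loading profiles for the 1-D solver.

#' Electrode specification
#'
#' A linearly tapered electrode inserted along the scala tympani from the
#' round window (`x = 0`) up to the arc length corresponding to
#' `insertion_angle_deg` on the cochlear spiral. Diameters default to a
#' human lateral-wall long-array taper scaled by the cochlear-length ratio;
#' they are stated defaults, not measured chinchilla values.
#'
#' @param insertion_angle_deg Insertion angle, degrees, in `[0, 900]`.
#' @param basal_diameter_mm,apical_diameter_mm Electrode diameter at the
#'   round-window end and at the inserted tip, mm (`basal >= apical`).
#' @param E,density,beta Electrode material: Young's modulus (Pa), density
#'   (kg/m^3) and Rayleigh beta damping (s). Defaults are taken from the
#'   electrode row of [material_table()].
#' @param mass_loading If `TRUE`, the electrode body's mass is added to the
#'   partition mass over the inserted span (sensitivity mode). Default
#'   `FALSE`: the electrode acts through duct occlusion plus its compliant
#'   lossy cross-section.
#' @param compliance_factor Order-one factor on the electrode's radial
#'   compliance in the shunt branch.
#' @param section_size_deg Sweep granularity, degrees (default 180).
#' @return An object of class `electrode_spec`.
#' @export
electrode_spec <- function(insertion_angle_deg = 900,
                           basal_diameter_mm = 0.55,
                           apical_diameter_mm = 0.25,
                           E = NULL, density = NULL, beta = NULL,
                           mass_loading = FALSE, compliance_factor = 1,
                           section_size_deg = 180) {
  if (insertion_angle_deg < 0 || insertion_angle_deg > 900) {
    stop("insertion_angle_deg must lie in [0, 900]")
  }
  if (basal_diameter_mm <= 0 || apical_diameter_mm <= 0) {
    stop("electrode diameters must be positive")
  }
  if (basal_diameter_mm < apical_diameter_mm) {
    stop("basal_diameter_mm must be >= apical_diameter_mm")
  }
  defaults <- material_table(quiet = TRUE)$electrode
  structure(list(insertion_angle_deg = insertion_angle_deg,
                 basal_diameter_mm = basal_diameter_mm,
                 apical_diameter_mm = apical_diameter_mm,
                 E = if (is.null(E)) defaults$E else E,
                 density = if (is.null(density)) defaults$density else density,
                 beta = if (is.null(beta)) defaults$beta else beta,
                 mass_loading = isTRUE(mass_loading),
                 compliance_factor = compliance_factor,
                 section_size_deg = section_size_deg),
            class = "electrode_spec")
}

#' Place an electrode in the scala tympani
#'
#' Translates an [electrode_spec()] into per-grid-node loading profiles: the
#' occlusion fraction `phi(x)` of the scala-tympani cross-section, the
#' electrode cross-section area, and (optionally) added partition mass. The
#' inserted span runs from the base to the arc length of the insertion angle;
#' the electrode taper is linear in arc length over that span, and the
#' occlusion ramps to zero over the final grid cell so the tip does not
#' introduce a numerical discontinuity.
#'
#' @param geom A [build_geometry()] result.
#' @param spec An [electrode_spec()].
#' @return An object of class `occlusion_profile` with fields `x` (mm),
#'   `phi` (fraction of `A_st` occluded, in `[0, 1)`), `A_e_mm2` (electrode
#'   cross-section on the grid), `added_mass` (kg/m^2 on the partition; zero
#'   unless `mass_loading`), `span_mm` (inserted arc length), `angle_deg`
#'   and the material constants carried into the solver.
#' @export
place_electrode <- function(geom, spec) {
  stopifnot(inherits(geom, "cochlear_geometry"),
            inherits(spec, "electrode_spec"))
  if (spec$insertion_angle_deg > geom$spiral$total_angle_deg) {
    stop("insertion angle exceeds the spiral's total angle")
  }
  x <- geom$x
  n <- length(x)
  phi <- numeric(n)
  A_e <- numeric(n)
  span <- 0
  if (spec$insertion_angle_deg > 0) {
    span <- geom$scale *
      angle_to_arclength(geom$spiral, spec$insertion_angle_deg)
    inside <- x <= span
    dia <- spec$basal_diameter_mm +
      (spec$apical_diameter_mm - spec$basal_diameter_mm) * x[inside] / span
    A_e[inside] <- pi * (dia / 2)^2
    # tip ramp over one grid cell
    dx <- geom$grid$dx_mm
    ramp <- pmin(1, pmax(0, (span - x) / dx))
    A_e <- A_e * ramp
    phi <- A_e / geom$A_st_mm2
    if (any(phi >= 1)) {
      i <- which(phi >= 1)[1]
      stop(sprintf(paste0("electrode cross-section (%.3g mm^2) meets or ",
                          "exceeds the scala-tympani area (%.3g mm^2) at ",
                          "x = %.3f mm"),
                   A_e[i], geom$A_st_mm2[i], x[i]))
    }
  }
  added_mass <- numeric(n)
  if (spec$mass_loading) {
    # electrode mass spread over the BM width per unit length
    added_mass <- spec$density * (A_e * 1e-6) / (geom$w_mm * 1e-3)
  }
  structure(list(x = x, phi = phi, A_e_mm2 = A_e, added_mass = added_mass,
                 span_mm = span,
                 angle_deg = spec$insertion_angle_deg,
                 E = spec$E, density = spec$density, beta = spec$beta,
                 compliance_factor = spec$compliance_factor,
                 mass_loading = spec$mass_loading),
            class = "occlusion_profile")
}

#' @export
print.occlusion_profile <- function(x, ...) {
  cat(sprintf(paste0("occlusion_profile: %g deg insertion, span %.2f mm, ",
                     "max phi = %.3f\n"),
              x$angle_deg, x$span_mm, max(x$phi)))
  invisible(x)
}

#' Sweep electrode insertion angles
#'
#' One occlusion profile per requested angle, in the given order. The default
#' angle list covers the study's insertion-depth sweep, 180 to 900 degrees in
#' 180-degree steps.
#'
#' @param geom A [build_geometry()] result.
#' @param base_spec An [electrode_spec()] whose angle is replaced per sweep
#'   entry.
#' @param angles_deg Numeric vector of insertion angles, degrees.
#' @return A named list of `occlusion_profile` objects
#'   (`"180"`, `"360"`, ...).
#' @export
sweep_angles <- function(geom, base_spec = electrode_spec(),
                         angles_deg = c(180, 360, 540, 720, 900)) {
  stopifnot(inherits(base_spec, "electrode_spec"))
  if (any(angles_deg < 0 | angles_deg > 900)) {
    stop("all sweep angles must lie in [0, 900]")
  }
  out <- lapply(angles_deg, function(a) {
    s <- base_spec
    s$insertion_angle_deg <- a
    place_electrode(geom, s)
  })
  names(out) <- as.character(angles_deg)
  out
}

#' Export an occlusion profile to CSV
#'
#' Columns: `x_mm, angle_deg, occlusion_fraction`.
#'
#' @param occ An `occlusion_profile`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_occlusion_csv <- function(occ, path) {
  stopifnot(inherits(occ, "occlusion_profile"))
  utils::write.csv(data.frame(x_mm = occ$x, angle_deg = occ$angle_deg,
                              occlusion_fraction = occ$phi),
                   path, row.names = FALSE)
  invisible(path)
}
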