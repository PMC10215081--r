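# Material constants and graded laws for every modelled structure, and their
# reduction to the per-position partition impedance parameters used by the
# harmonic solver. Position x is in mm from the basal end of the BM midline;
# the exponential/linear law arguments use these units (with the 18.3 mm
# chinchilla length this yields a ~47x basal-apical modulus gradient).

#' Full material table
#'
#' All mechanical constants of the model, grouped by structure. The basilar
#' membrane (BM) and Reissner's membrane (RM) carry position-dependent
#' elastic-modulus and Rayleigh stiffness-proportional damping (beta) laws;
#' every other structure carries plain constants. Vestibular structures
#' (cupulae, maculae, membranous labyrinth) and bone are stored for
#' completeness but take no part in the solved system (the bony walls are
#' rigid). Any entry can be overridden.
#'
#' The printed lymphatic-fluid bulk modulus (2.6e9 Pa) and speed of sound
#' (1498 m/s) are mutually inconsistent at density 1000 kg/m^3
#' (`sqrt(K/rho)` = 1612 m/s); construction surfaces this as a warning and
#' the solver treats the speed of sound as primary. Bone carries two
#' published moduli (`E` = 13.4e10 Pa from the property table, `E_text` =
#' 14.1e9 Pa from the accompanying description); neither is used.
#'
#' @param overrides Named nested list merged over the defaults, e.g.
#'   `list(bm = list(E0 = 8e4))`.
#' @param fluid_tol Relative tolerance for the fluid speed-of-sound
#'   consistency check. Default 0.02.
#' @param quiet Suppress the consistency warning.
#' @return An object of class `material_table`.
#' @examples
#' mat <- suppressWarnings(material_table())
#' mat$electrode$E
#' bm_modulus(0, mat)
#' @export
material_table <- function(overrides = NULL, fluid_tol = 0.02, quiet = FALSE) {
  mat <- list(
    bm = list(density = 1e3, E0 = 7.1e4, E_rate = -0.21,
              beta0 = 2.3e-8, beta_rate = 0.52, nu = 0.4),
    rm = list(density = 1e3, E_slope = 1e4, E_floor_mm = 0.1,
              beta0 = 6e-6, beta_rate = 0.158, nu = 0.4),
    cupula = list(density = 1e3, E = 2.8),
    macula_gel = list(density = 1e3, E = 10),
    macula_otoconial = list(density = 2.71e3, E = 500),
    bone = list(density = 1.2e3, E = 13.4e10, E_text = 14.1e9, beta = 0.45),
    membranous_labyrinth = list(density = 1e3, E = 1.3e4, beta = 0.14),
    fluid = list(density = 1e3, bulk_modulus = 2.6e9, beta = 1.5e-4,
                 viscosity = 1e-3, speed_of_sound = 1498),
    owm = list(density = 1e3, E = 3.5e5, beta = 5e-4),
    rwm = list(density = 1.5e3, E = 3.5e5, beta = 5e-4),
    electrode = list(density = 3.4e3, E = 4e5, beta = 7.7e-2)
  )
  if (!is.null(overrides)) {
    for (s in names(overrides)) {
      if (!s %in% names(mat)) stop("unknown material structure: ", s)
      for (p in names(overrides[[s]])) mat[[s]][[p]] <- overrides[[s]][[p]]
    }
  }
  for (s in names(mat)) {
    if (mat[[s]]$density <= 0) stop("non-positive density for ", s)
  }
  if (mat$bm$nu <= 0 || mat$bm$nu >= 0.5) stop("bm nu must be in (0, 0.5)")
  if (mat$rm$nu <= 0 || mat$rm$nu >= 0.5) stop("rm nu must be in (0, 0.5)")
  c_from_K <- sqrt(mat$fluid$bulk_modulus / mat$fluid$density)
  rel <- abs(c_from_K - mat$fluid$speed_of_sound) / mat$fluid$speed_of_sound
  if (rel > fluid_tol && !quiet) {
    warning(sprintf(paste0(
      "fluid bulk modulus and speed of sound are inconsistent: ",
      "sqrt(K/rho) = %.0f m/s vs c = %.0f m/s (%.1f%% off); ",
      "the solver takes c as primary"),
      c_from_K, mat$fluid$speed_of_sound, 100 * rel), call. = FALSE)
  }
  structure(mat, class = "material_table")
}

#' @export
print.material_table <- function(x, ...) {
  cat("material_table:", length(unclass(x)), "structures\n")
  cat("  BM E(x) =", format(x$bm$E0), "* exp(", x$bm$E_rate, "x ) Pa,",
      "beta(x) =", format(x$bm$beta0), "* exp(", x$bm$beta_rate, "x )\n")
  cat("  electrode E =", format(x$electrode$E), "Pa, rho =",
      x$electrode$density, "kg/m^3\n")
  invisible(x)
}

check_x_range <- function(x_mm, L = 18.3) {
  if (any(!is.finite(x_mm)) || any(x_mm < 0) || any(x_mm > L)) {
    stop("x_mm out of range [0, ", L, "]")
  }
}

#' Basilar-membrane elastic modulus law
#'
#' `E(x) = E0 * exp(E_rate * x)` with `x` in mm from the base; the default
#' coefficients give 7.1e4 Pa at the base decaying by factor ~47 over the
#' 18.3 mm chinchilla BM.
#'
#' @param x_mm Position(s) from the base, mm.
#' @param mat A [material_table()].
#' @param L Domain length used for range validation, mm.
#' @return Modulus in Pa.
#' @export
bm_modulus <- function(x_mm, mat = material_table(quiet = TRUE), L = 18.3) {
  check_x_range(x_mm, L)
  mat$bm$E0 * exp(mat$bm$E_rate * x_mm)
}

#' Basilar-membrane damping-coefficient law
#'
#' Stiffness-proportional Rayleigh damping `beta(x) = beta0 * exp(beta_rate *
#' x)` in seconds, entering the harmonic analysis as the complex modulus
#' `E * (1 + i * omega * beta)`.
#'
#' @inheritParams bm_modulus
#' @return Dimensionless-per-rad/s damping coefficient (seconds).
#' @export
bm_damping <- function(x_mm, mat = material_table(quiet = TRUE), L = 18.3) {
  check_x_range(x_mm, L)
  mat$bm$beta0 * exp(mat$bm$beta_rate * x_mm)
}

#' Reissner's-membrane elastic modulus law
#'
#' Linear law `E(x) = E_slope * max(x, floor)` with a small positional floor
#' so the modulus never evaluates to zero at the base. The RM is carried as a
#' parameter but is mechanically inert in the two-duct reduction.
#'
#' @inheritParams bm_modulus
#' @return Modulus in Pa.
#' @export
rm_modulus <- function(x_mm, mat = material_table(quiet = TRUE), L = 18.3) {
  check_x_range(x_mm, L)
  mat$rm$E_slope * pmax(x_mm, mat$rm$E_floor_mm)
}

#' Reissner's-membrane damping-coefficient law
#'
#' @inheritParams bm_modulus
#' @return Damping coefficient (seconds).
#' @export
rm_damping <- function(x_mm, mat = material_table(quiet = TRUE), L = 18.3) {
  check_x_range(x_mm, L)
  mat$rm$beta0 * exp(mat$rm$beta_rate * x_mm)
}

#' Per-position partition impedance parameters
#'
#' Reduces the graded elastic BM to a locally reacting partition on the
#' geometry grid: stiffness per unit area `K(x) = C * E(x) * t(x)^3 /
#' ((1 - nu^2) * w(x)^4)` (clamped-strip plate reduction; `C` is the plate
#' constant, see Details), mass per unit area `m(x) = rho * t(x)`, and the
#' damping law `beta(x)`. The solver forms the complex stiffness
#' `K * (1 + i * omega * beta)` per frequency.
#'
#' @details The plate constant folds every effect the strip reduction cannot
#' represent (edge conditions, transverse fiber anisotropy, the arcuate/
#' pectinate division) into one scalar. A homogeneous clamped strip under
#' uniform load gives `C = 60` on the mean-deflection convention; measured
#' BM point stiffness exceeds the homogeneous-plate estimate, so the default
#' `C = 175` is calibrated once so that the basal cutoff frequency
#' `sqrt(K(0)/m(0))/2pi` of the default geometry equals the Greenwood
#' chinchilla base characteristic frequency (~20.4 kHz). It is configurable.
#'
#' @param geom A [build_geometry()] result.
#' @param mat A [material_table()].
#' @param plate_constant Dimensionless plate constant `C`.
#' @return An object of class `partition_params` with fields `x` (mm),
#'   `K` (Pa/m), `m` (kg/m^2), `beta` (s), `w_m` (BM width, m) and the
#'   inputs used.
#' @export
partition_params <- function(geom, mat = material_table(quiet = TRUE),
                             plate_constant = 175) {
  stopifnot(inherits(geom, "cochlear_geometry"),
            inherits(mat, "material_table"))
  if (plate_constant <= 0) stop("plate_constant must be positive")
  x <- geom$x
  E <- bm_modulus(x, mat, L = geom$L)
  beta <- bm_damping(x, mat, L = geom$L)
  t_m <- geom$t_um * 1e-6
  w_m <- geom$w_mm * 1e-3
  K <- plate_constant * E * t_m^3 / ((1 - mat$bm$nu^2) * w_m^4)
  m <- mat$bm$density * t_m
  structure(list(x = x, K = K, m = m, beta = beta, w_m = w_m,
                 plate_constant = plate_constant, nu = mat$bm$nu),
            class = "partition_params")
}

#' @export
print.partition_params <- function(x, ...) {
  n <- length(x$x)
  cat("partition_params:", n, "nodes\n")
  cat(sprintf("  K: %.3g -> %.3g Pa/m   m: %.3g -> %.3g kg/m^2\n",
              x$K[1], x$K[n], x$m[1], x$m[n]))
  cat(sprintf("  basal cutoff sqrt(K/m)/2pi = %.0f Hz, apical %.0f Hz\n",
              sqrt(x$K[1] / x$m[1]) / (2 * pi),
              sqrt(x$K[n] / x$m[n]) / (2 * pi)))
  invisible(x)
}

#' Dump the material table to CSV for audit
#'
#' One row per (structure, parameter, value) triple, mirroring the model's
#' property table.
#'
#' @param mat A [material_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_material_csv <- function(mat, path) {
  stopifnot(inherits(mat, "material_table"))
  rows <- do.call(rbind, lapply(names(unclass(mat)), function(s) {
    pars <- mat[[s]]
    data.frame(structure = s, parameter = names(pars),
               value = unlist(pars, use.names = FALSE))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
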