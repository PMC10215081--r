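# Reproducible run orchestration: structured YAML configs, validation, the
# two headline experiments (healthy run, insertion-angle sweep) and fixture
# generation. Every run writes a self-contained output directory: config
# echo, geometry/material dumps, response and tuning CSVs, a run log and a
# checksum manifest. All runs are deterministic from the config alone.

#' Default run configuration
#'
#' The full nested configuration with every tunable of the model at its
#' default. Blocks: `geometry`, `materials`, `electrode`, `stimulus`,
#' `solver`, `analysis`, `sweep`.
#'
#' @return A nested list.
#' @examples
#' cfg <- default_config()
#' cfg$geometry$length_mm
#' @export
default_config <- function() {
  list(
    geometry = list(
      length_mm = 18.3, dx_mm = 0.0025,
      thickness_base_um = 16.5, thickness_apex_um = 5,
      width_base_mm = 0.125, width_apex_mm = 0.25,
      area_sv_base_mm2 = 0.8, area_sv_apex_mm2 = 0.3,
      area_st_base_mm2 = 0.8, area_st_apex_mm2 = 0.3,
      thickness_profile = "linear",
      spiral = list(form = "logarithmic", total_angle_deg = 1080,
                    basal_radius_mm = 2, taper_rate = 0.12)
    ),
    materials = list(plate_constant = 175, overrides = NULL),
    electrode = list(insertion_angle_deg = 900,
                     basal_diameter_mm = 0.55, apical_diameter_mm = 0.25,
                     mass_loading = FALSE, compliance_factor = 1),
    stimulus = list(frequencies_Hz = c(400, 1000, 2000, 4000, 6000, 8000,
                                       10000),
                    stapes_displacement_m = 1e-8,
                    level_label = "90 dB SPL"),
    solver = list(formulation = "incompressible", helicotrema = "matched",
                  footplate_area_mm2 = 1, tolerance = 1e-10),
    analysis = list(smoothing_window_mm = 0.2,
                    greenwood = list(species = "chinchilla"),
                    max_dx_shift_mm = 0.1, max_ddb = 3,
                    greenwood_rms_fraction = 0.05),
    sweep = list(angles_deg = c(180, 360, 540, 720, 900))
  )
}

#' Toy run configuration
#'
#' A miniature cochlea (2 mm, 51 nodes, single 1 kHz tone) for fast smoke
#' tests and the packaged regression fixture.
#'
#' @return A nested list as in [default_config()].
#' @export
toy_config <- function() {
  cfg <- default_config()
  cfg$geometry$length_mm <- 2
  cfg$geometry$dx_mm <- 0.04
  cfg$stimulus$frequencies_Hz <- 1000
  cfg$electrode$insertion_angle_deg <- 180
  cfg$electrode$basal_diameter_mm <- 0.3
  cfg$electrode$apical_diameter_mm <- 0.2
  cfg$sweep$angles_deg <- c(90, 180)
  cfg
}

# deep-merge a partial user config over the defaults
merge_config <- function(cfg, base = default_config()) {
  if (is.null(cfg)) return(base)
  utils::modifyList(base, cfg)
}

# names of leaves where cfg departs from the defaults (dotted paths)
config_overrides <- function(cfg, base = default_config(), prefix = "") {
  out <- character(0)
  for (nm in union(names(base), names(cfg))) {
    path <- if (prefix == "") nm else paste0(prefix, ".", nm)
    a <- base[[nm]]
    b <- cfg[[nm]]
    if (is.list(a) || is.list(b)) {
      out <- c(out, config_overrides(if (is.list(b)) b else list(),
                                     if (is.list(a)) a else list(), path))
    } else if (!identical(a, b)) {
      out <- c(out, path)
    }
  }
  out
}

#' Read a run configuration from a YAML file
#'
#' Partial configs are allowed: anything not given takes its default.
#'
#' @param path YAML file path.
#' @return The merged, validated configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- merge_config(yaml::read_yaml(path))
  validate_config(cfg)
  cfg
}

#' Validate a run configuration
#'
#' Instantiates every model object implied by the config so that any invalid
#' field fails here, before computation, with a message naming it.
#'
#' @param cfg A configuration list (see [default_config()]).
#' @return `TRUE`, invisibly; errors otherwise.
#' @export
validate_config <- function(cfg) {
  objs <- config_objects(cfg)
  stopifnot(inherits(objs$geom, "cochlear_geometry"))
  invisible(TRUE)
}

# instantiate all model objects from a config
config_objects <- function(cfg) {
  cfg <- merge_config(cfg)
  g <- cfg$geometry
  sp <- g$spiral
  geom <- build_geometry(
    length_mm = g$length_mm,
    spiral = spiral_spec(total_angle_deg = sp$total_angle_deg,
                         basal_radius_mm = sp$basal_radius_mm,
                         taper_rate = sp$taper_rate, form = sp$form),
    grid = grid_spec(g$dx_mm),
    thickness_base_um = g$thickness_base_um,
    thickness_apex_um = g$thickness_apex_um,
    width_base_mm = g$width_base_mm, width_apex_mm = g$width_apex_mm,
    area_sv_base_mm2 = g$area_sv_base_mm2,
    area_sv_apex_mm2 = g$area_sv_apex_mm2,
    area_st_base_mm2 = g$area_st_base_mm2,
    area_st_apex_mm2 = g$area_st_apex_mm2,
    thickness_profile = g$thickness_profile)
  mat <- material_table(overrides = cfg$materials$overrides, quiet = TRUE)
  e <- cfg$electrode
  espec <- electrode_spec(insertion_angle_deg = e$insertion_angle_deg,
                          basal_diameter_mm = e$basal_diameter_mm,
                          apical_diameter_mm = e$apical_diameter_mm,
                          mass_loading = e$mass_loading,
                          compliance_factor = e$compliance_factor)
  s <- cfg$stimulus
  stim <- stimulus_spec(frequencies_Hz = s$frequencies_Hz,
                        stapes_displacement_m = s$stapes_displacement_m,
                        level_label = s$level_label)
  so <- cfg$solver
  settings <- solver_settings(formulation = so$formulation,
                              helicotrema = so$helicotrema,
                              footplate_area_mm2 = so$footplate_area_mm2,
                              tolerance = so$tolerance)
  list(cfg = cfg, geom = geom, mat = mat, espec = espec, stim = stim,
       settings = settings,
       plate_constant = cfg$materials$plate_constant,
       analysis = cfg$analysis, sweep = cfg$sweep)
}

run_log <- function(outdir) {
  logfile <- file.path(outdir, "run.log")
  function(...) {
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ", sprintf(...), "\n",
        sep = "", file = logfile, append = TRUE)
  }
}

write_manifest <- function(outdir, files) {
  paths <- file.path(outdir, files)
  sums <- tools::md5sum(paths)
  manifest <- list(files = files, md5 = unname(sums))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = FALSE, pretty = TRUE)
  invisible(manifest)
}

setup_run <- function(cfg, outdir) {
  cfg <- merge_config(cfg)
  validate_config(cfg)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log <- run_log(outdir)
  yaml::write_yaml(cfg, file.path(outdir, "config_echo.yaml"))
  ov <- config_overrides(cfg)
  log("config checksum %s",
      unname(tools::md5sum(file.path(outdir, "config_echo.yaml"))))
  if (length(ov)) log("overridden defaults: %s", paste(ov, collapse = ", "))
  else log("all defaults")
  list(cfg = cfg, log = log)
}

#' Run the healthy (unimplanted) pipeline
#'
#' Builds geometry and materials from the config, solves the harmonic
#' response at every stimulus frequency, extracts the tuning map and its
#' Greenwood comparison, and writes `config_echo.yaml`, `geometry.csv`,
#' `materials.csv`, `response_healthy.csv`, `tuning_healthy.csv`,
#' `manifest.json` and `run.log` into `outdir`.
#'
#' @param cfg Configuration list (partial configs are merged over defaults).
#' @param outdir Output directory, created if needed.
#' @return Invisibly, a list with `resp` (`bm_response`), `tuning`
#'   (with Greenwood columns) and `outdir`.
#' @export
run_healthy <- function(cfg = default_config(), outdir = tempfile("healthy_")) {
  st <- setup_run(cfg, outdir)
  cfg <- st$cfg
  o <- config_objects(cfg)
  st$log("geometry: L = %g mm, %d nodes", o$geom$L, length(o$geom$x))
  write_geometry_csv(o$geom, file.path(outdir, "geometry.csv"))
  write_material_csv(o$mat, file.path(outdir, "materials.csv"))
  resp <- solve_harmonic(o$geom, o$mat, occ = NULL, stim = o$stim,
                         settings = o$settings,
                         plate_constant = o$plate_constant)
  st$log("healthy solve: %d frequencies, max residual %.3e",
         length(o$stim$frequencies_Hz), max(resp$diagnostics$residual))
  write_response_csv(resp, file.path(outdir, "response_healthy.csv"))
  tuning <- compare_greenwood(
    extract_tuning(resp, window_mm = o$analysis$smoothing_window_mm),
    greenwood_map(species = o$analysis$greenwood$species))
  write_tuning_csv(tuning, file.path(outdir, "tuning_healthy.csv"))
  st$log("tuning: RMS Greenwood location error %.3f mm",
         attr(tuning, "rms_mm"))
  write_manifest(outdir, c("config_echo.yaml", "geometry.csv",
                           "materials.csv", "response_healthy.csv",
                           "tuning_healthy.csv"))
  invisible(list(resp = resp, tuning = tuning, outdir = outdir))
}

#' Run the insertion-angle sweep
#'
#' The healthy pipeline plus one implanted solve per sweep angle, and the
#' residual-hearing delta table (canonically ordered by angle then
#' frequency) written as `deltas.csv`. Per-angle responses and tuning maps
#' are written as `response_angle_<deg>.csv` / `tuning_angle_<deg>.csv`.
#'
#' @inheritParams run_healthy
#' @return Invisibly, a list with `healthy`, `implanted` (list keyed by
#'   angle), `deltas` (data.frame), and `outdir`.
#' @export
run_sweep <- function(cfg = default_config(), outdir = tempfile("sweep_")) {
  st <- setup_run(cfg, outdir)
  cfg <- st$cfg
  o <- config_objects(cfg)
  write_geometry_csv(o$geom, file.path(outdir, "geometry.csv"))
  write_material_csv(o$mat, file.path(outdir, "materials.csv"))
  resp_h <- solve_harmonic(o$geom, o$mat, occ = NULL, stim = o$stim,
                           settings = o$settings,
                           plate_constant = o$plate_constant)
  write_response_csv(resp_h, file.path(outdir, "response_healthy.csv"))
  tuning_h <- extract_tuning(resp_h,
                             window_mm = o$analysis$smoothing_window_mm)
  write_tuning_csv(tuning_h, file.path(outdir, "tuning_healthy.csv"))
  st$log("healthy solve done")

  angles <- sort(o$sweep$angles_deg)
  occs <- sweep_angles(o$geom, o$espec, angles)
  implanted <- list()
  deltas <- list()
  files <- c("config_echo.yaml", "geometry.csv", "materials.csv",
             "response_healthy.csv", "tuning_healthy.csv")
  for (a in names(occs)) {
    resp_i <- solve_harmonic(o$geom, o$mat, occ = occs[[a]], stim = o$stim,
                             settings = o$settings,
                             plate_constant = o$plate_constant)
    tuning_i <- extract_tuning(resp_i,
                               window_mm = o$analysis$smoothing_window_mm)
    fr <- sprintf("response_angle_%s.csv", a)
    ft <- sprintf("tuning_angle_%s.csv", a)
    write_response_csv(resp_i, file.path(outdir, fr))
    write_tuning_csv(tuning_i, file.path(outdir, ft))
    files <- c(files, fr, ft)
    implanted[[a]] <- list(resp = resp_i, tuning = tuning_i)
    deltas[[a]] <- residual_hearing_delta(tuning_h, tuning_i)
    st$log("angle %s deg: max |dx| = %.4f mm, max |ddB| = %.3f dB", a,
           attr(deltas[[a]], "max_abs_dx_mm"),
           attr(deltas[[a]], "max_abs_ddB"))
  }
  delta_tab <- do.call(rbind, lapply(deltas, as.data.frame))
  delta_tab <- delta_tab[order(delta_tab$angle_deg, delta_tab$frequency_Hz), ]
  rownames(delta_tab) <- NULL
  utils::write.csv(delta_tab, file.path(outdir, "deltas.csv"),
                   row.names = FALSE)
  files <- c(files, "deltas.csv")
  write_manifest(outdir, files)
  invisible(list(healthy = list(resp = resp_h, tuning = tuning_h),
                 implanted = implanted, deltas = delta_tab, outdir = outdir))
}

#' Write packaged fixture configs
#'
#' Writes `toy_config.yaml` and/or `default_config.yaml` into a directory.
#' Fixture generation is seed-free and deterministic.
#'
#' @param dir Target directory.
#' @param size `"toy"`, `"default"` or `"both"`.
#' @return Character vector of the written paths, invisibly.
#' @export
make_fixtures <- function(dir = ".", size = c("both", "toy", "default")) {
  size <- match.arg(size)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- character(0)
  if (size %in% c("toy", "both")) {
    p <- file.path(dir, "toy_config.yaml")
    yaml::write_yaml(toy_config(), p)
    out <- c(out, p)
  }
  if (size %in% c("default", "both")) {
    p <- file.path(dir, "default_config.yaml")
    yaml::write_yaml(default_config(), p)
    out <- c(out, p)
  }
  invisible(out)
}

#' Command-line entry point
#'
#' Dispatches the subcommands `healthy`, `sweep`, `fixtures` and
#' `validate-config` with options `--config PATH`, `--outdir PATH` and
#' `--log-level LEVEL`. Used by the installed `exec/cochlear` script.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status: 0 ok, 1 configuration error, 2 runtime error.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: cochlear <healthy|sweep|fixtures|validate-config>",
    "[--config PATH] [--outdir PATH] [--log-level LEVEL]")
  if (length(args) < 1) {
    message(usage)
    return(1L)
  }
  cmd <- args[1]
  opts <- list(config = NULL, outdir = "cochlear_run", `log-level` = "info")
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opts) || i + 1 > length(args)) {
      message("unknown or incomplete option: ", args[i], "\n", usage)
      return(1L)
    }
    opts[[key]] <- args[i + 1]
    i <- i + 2
  }
  cfg <- tryCatch({
    if (is.null(opts$config)) default_config() else read_run_config(opts$config)
  }, error = function(e) {
    message("configuration error: ", conditionMessage(e))
    NULL
  })
  if (is.null(cfg)) return(1L)
  switch(cmd,
    "validate-config" = {
      ok <- tryCatch(validate_config(cfg), error = function(e) {
        message("configuration error: ", conditionMessage(e))
        FALSE
      })
      if (isTRUE(ok)) {
        message("config ok")
        return(0L)
      }
      return(1L)
    },
    "healthy" = ,
    "sweep" = {
      res <- tryCatch({
        if (cmd == "healthy") run_healthy(cfg, opts$outdir)
        else run_sweep(cfg, opts$outdir)
        0L
      }, error = function(e) {
        message("runtime error: ", conditionMessage(e))
        2L
      })
      if (res == 0L) message("outputs written to ", opts$outdir)
      return(res)
    },
    "fixtures" = {
      res <- tryCatch({
        make_fixtures(opts$outdir)
        0L
      }, error = function(e) {
        message("runtime error: ", conditionMessage(e))
        2L
      })
      return(res)
    },
    {
      message("unknown subcommand: ", cmd, "\n", usage)
      return(1L)
    })
}
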