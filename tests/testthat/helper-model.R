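# shared fixtures: everything is built in code, no stored data

# coarse default-shaped cochlea, fast enough for unit tests
coarse_geom <- function(dx = 0.01, ...) {
  build_geometry(grid = grid_spec(dx), ...)
}

# spatially uniform cochlea (constant thickness/width/areas)
uniform_geom <- function(dx = 0.01, t_um = 10, w_mm = 0.2, A_mm2 = 0.5,
                         L = 18.3) {
  build_geometry(length_mm = L, grid = grid_spec(dx),
                 thickness_base_um = t_um, thickness_apex_um = t_um,
                 width_base_mm = w_mm, width_apex_mm = w_mm,
                 area_sv_base_mm2 = A_mm2, area_sv_apex_mm2 = A_mm2,
                 area_st_base_mm2 = A_mm2, area_st_apex_mm2 = A_mm2)
}

# material table with position-independent BM laws (E0, beta0 constants)
const_mat <- function(E0 = 5e4, beta0 = 1e-5) {
  material_table(overrides = list(bm = list(E0 = E0, E_rate = 0,
                                            beta0 = beta0, beta_rate = 0)),
                 quiet = TRUE)
}

quiet_mat <- function(...) material_table(..., quiet = TRUE)

# hand-assembled tuning_result for analysis unit tests
fake_tuning <- function(frequency_Hz, x_max_mm, normalized_peak,
                        L = 18.3, dx_mm = 0.01, angle_deg = NA_real_,
                        window_mm = 0.2) {
  out <- data.frame(frequency_Hz = frequency_Hz, x_max_mm = x_max_mm,
                    normalized_peak = normalized_peak, flagged = FALSE)
  attr(out, "L") <- L
  attr(out, "dx_mm") <- dx_mm
  attr(out, "angle_deg") <- angle_deg
  attr(out, "window_mm") <- window_mm
  class(out) <- c("tuning_result", "data.frame")
  out
}

# hand-assembled bm_response for analysis unit tests
fake_response <- function(x, u, us, frequencies_Hz) {
  structure(list(x = x, frequencies_Hz = frequencies_Hz,
                 u = u, us = us, angle_deg = NA_real_,
                 diagnostics = data.frame(frequency_Hz = frequencies_Hz,
                                          residual = 0,
                                          n_nodes = length(x))),
            class = "bm_response")
}
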