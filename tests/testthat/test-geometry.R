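test_that("default geometry satisfies the chinchilla dimension invariants", {
  geom <- coarse_geom()
  n <- length(geom$x)
  expect_identical(geom$L, 18.3)
  expect_identical(geom$x[1], 0)
  expect_equal(geom$x[n], 18.3)
  expect_true(all(diff(geom$x) > 0))
  expect_identical(geom$t_um[1], 16.5)
  expect_equal(geom$t_um[n], 5)
  expect_true(all(geom$t_um > 0) && all(geom$w_mm > 0))
  expect_true(all(geom$A_sv_mm2 > 0) && all(geom$A_st_mm2 > 0))
  expect_identical(geom$angle_deg[1], 0)
  expect_true(all(diff(geom$angle_deg) > 0))
})

test_that("thickness interpolation is pinned to the printed endpoints", {
  geom <- coarse_geom()
  expect_identical(thickness_at(geom, 0), 16.5)
  expect_equal(thickness_at(geom, geom$L), 5)
  expect_equal(thickness_at(geom, geom$L / 2), 10.75)
  xs <- seq(0, geom$L, length.out = 200)
  expect_true(all(diff(thickness_at(geom, xs)) <= 0))
  expect_error(thickness_at(geom, -0.1), "range")
  expect_error(thickness_at(geom, geom$L + 0.1), "range")
})

test_that("scaling to a doubled target length doubles all arc lengths", {
  sp <- spiral_spec()
  g1 <- coarse_geom(dx = 0.05)
  g2 <- build_geometry(length_mm = 36.6, grid = grid_spec(0.1), spiral = sp)
  expect_equal(g2$scale, 2 * g1$scale)
  # same spiral angle reached at exactly twice the arc length
  for (th in c(180, 540, 900)) {
    expect_equal(g2$scale * angle_to_arclength(sp, th),
                 2 * g1$scale * angle_to_arclength(sp, th))
  }
})

test_that("dimension profiles are independent of the pre-scale spiral size", {
  g1 <- build_geometry(spiral = spiral_spec(basal_radius_mm = 1),
                       grid = grid_spec(0.05))
  g2 <- build_geometry(spiral = spiral_spec(basal_radius_mm = 5),
                       grid = grid_spec(0.05))
  expect_identical(g1$t_um, g2$t_um)
  expect_identical(g1$w_mm, g2$w_mm)
  expect_identical(g1$A_sv_mm2, g2$A_sv_mm2)
})

test_that("arc length matches adaptive quadrature of the centerline speed", {
  for (form in c("logarithmic", "archimedean")) {
    sp <- spiral_spec(form = form, taper_rate = 0.04)
    r0 <- sp$basal_radius_mm
    b <- sp$taper_rate
    speed <- function(th_rad) {  # independent oracle, coded from the forms
      if (form == "logarithmic") {
        r0 * exp(-b * th_rad) * sqrt(1 + b^2)
      } else {
        sqrt((r0 * (1 - b * th_rad))^2 + (r0 * b)^2)
      }
    }
    oracle <- stats::integrate(speed, 0, 2 * pi, rel.tol = 1e-10)$value
    expect_equal(angle_to_arclength(sp, 360), oracle, tolerance = 1e-6)
    expect_identical(angle_to_arclength(sp, 0), 0)
    total <- stats::integrate(speed, 0, sp$total_angle_deg * pi / 180,
                              rel.tol = 1e-10)$value
    expect_equal(angle_to_arclength(sp, sp$total_angle_deg), total,
                 tolerance = 1e-6)
  }
})

test_that("numerical derivative of the arc-length map equals the speed", {
  sp <- spiral_spec()
  th <- seq(10, 1070, by = 30)
  h <- 0.01
  deriv <- (angle_to_arclength(sp, th + h) - angle_to_arclength(sp, th - h)) /
    (2 * h) * 180 / pi  # mm per radian
  speed <- sp$basal_radius_mm * exp(-sp$taper_rate * th * pi / 180) *
    sqrt(1 + sp$taper_rate^2)
  expect_true(all(abs(deriv / speed - 1) < 0.01))
})

test_that("angle/arc-length maps invert each other", {
  for (form in c("logarithmic", "archimedean")) {
    sp <- spiral_spec(form = form, taper_rate = 0.04)
    expect_identical(arclength_to_angle(sp, 0), 0)
    for (th in c(180, 540, 900)) {
      s <- angle_to_arclength(sp, th)
      expect_equal(arclength_to_angle(sp, s), th, tolerance = 1e-6)
    }
    # bisection oracle at half the total length
    s_half <- angle_to_arclength(sp, sp$total_angle_deg) / 2
    lo <- 0; hi <- sp$total_angle_deg
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (angle_to_arclength(sp, mid) < s_half) lo <- mid else hi <- mid
    }
    expect_equal(arclength_to_angle(sp, s_half), (lo + hi) / 2,
                 tolerance = 1e-6)
  }
})

test_that("invalid geometry inputs are rejected with the field named", {
  expect_error(build_geometry(width_base_mm = -1), "width_base_mm")
  expect_error(build_geometry(length_mm = 0), "length_mm")
  expect_error(build_geometry(thickness_apex_um = 0), "thickness_apex_um")
  expect_error(spiral_spec(total_angle_deg = 720), "900")
  expect_error(grid_spec(0.6), "dx_mm")
  expect_error(angle_to_arclength(spiral_spec(), 1100), "range")
  expect_error(arclength_to_angle(spiral_spec(), -1), "range")
})

test_that("geometry exports round-trip through CSV and valid VTK", {
  geom <- coarse_geom(dx = 0.05)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_geometry_csv(geom, csv)
  df <- read.csv(csv)
  expect_equal(df$x_mm, geom$x)
  expect_equal(df$thickness_um, geom$t_um)
  expect_equal(df$angle_deg, geom$angle_deg)

  vtk <- withr::local_tempfile(fileext = ".vtk")
  write_geometry_vtk(geom, vtk)
  lines <- readLines(vtk)
  expect_match(lines[1], "^# vtk DataFile")
  expect_match(lines[5], sprintf("^POINTS %d double$", length(geom$x)))
  expect_true(any(grepl("^SCALARS thickness_um", lines)))
})
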