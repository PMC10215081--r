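test_that("tridiagonal solver matches hand-solved small systems", {
  # 2x2: Cramer's rule as the independent oracle
  sys2 <- structure(list(lower = 3 - 1i, diag = c(2 + 1i, 4 - 2i),
                         upper = 1 + 2i, rhs = c(1 + 0i, -2 + 3i)),
                    class = "cochlea_system")
  det2 <- (2 + 1i) * (4 - 2i) - (1 + 2i) * (3 - 1i)
  hand <- c(((1 + 0i) * (4 - 2i) - (1 + 2i) * (-2 + 3i)) / det2,
            ((2 + 1i) * (-2 + 3i) - (1 + 0i) * (3 - 1i)) / det2)
  expect_equal(cochleaR:::solve_system(sys2), hand, tolerance = 1e-14)

  # larger random tridiagonal vs dense solve
  set.seed(42)
  n <- 12
  rc <- function(k) complex(real = rnorm(k), imaginary = rnorm(k))
  lower <- rc(n - 1); upper <- rc(n - 1)
  diagv <- rc(n) + 6  # diagonally dominant
  rhs <- rc(n)
  A <- diag(diagv)
  A[cbind(2:n, 1:(n - 1))] <- lower
  A[cbind(1:(n - 1), 2:n)] <- upper
  sysn <- structure(list(lower = lower, diag = diagv, upper = upper,
                         rhs = rhs), class = "cochlea_system")
  expect_equal(cochleaR:::solve_system(sysn), as.vector(solve(A, rhs)),
               tolerance = 1e-12)

  singular <- structure(list(lower = 0 + 0i, diag = c(0 + 0i, 1 + 0i),
                             upper = 0 + 0i, rhs = c(1 + 0i, 1 + 0i)),
                        class = "cochlea_system")
  expect_error(cochleaR:::solve_system(singular), "singular")
})

test_that("a uniform duct assembles a symmetric tridiagonal system", {
  geom <- uniform_geom(dx = 0.05)
  pp <- partition_params(geom, const_mat(beta0 = 0))
  sys <- assemble_system(geom, pp, f = 200)  # below the uniform resonance
  expect_identical(sys$lower, sys$upper)
  expect_length(sys$diag, length(geom$x))
  expect_identical(sys$rhs[-1], complex(length(geom$x) - 1))
})

test_that("a zero-angle electrode reproduces the healthy system exactly", {
  geom <- coarse_geom(dx = 0.05)
  mat <- quiet_mat()
  pp <- partition_params(geom, mat)
  occ0 <- place_electrode(geom, electrode_spec(insertion_angle_deg = 0))
  s_h <- assemble_system(geom, pp, f = 1000)
  s_0 <- assemble_system(geom, pp, f = 1000, occ = occ0)
  expect_identical(s_h$lower, s_0$lower)
  expect_identical(s_h$diag, s_0$diag)
  expect_identical(s_h$rhs, s_0$rhs)
  r_h <- solve_harmonic(geom, mat, stim = stimulus_spec(frequencies_Hz = 1000))
  r_0 <- solve_harmonic(geom, mat, occ = occ0,
                        stim = stimulus_spec(frequencies_Hz = 1000))
  expect_identical(r_h$u, r_0$u)
})

test_that("the harmonic response is linear in the drive", {
  geom <- coarse_geom(dx = 0.05)
  mat <- quiet_mat()
  r1 <- solve_harmonic(geom, mat,
                       stim = stimulus_spec(frequencies_Hz = c(1000, 6000)))
  r2 <- solve_harmonic(geom, mat,
                       stim = stimulus_spec(frequencies_Hz = c(1000, 6000),
                                            stapes_displacement_m = 2e-8))
  expect_lt(max(abs(r2$u - 2 * r1$u) / abs(r1$u)), 1e-12)

  # phase rotation of the drive rotates the solution identically
  pp <- partition_params(geom, mat)
  sys <- assemble_system(geom, pp, f = 1000)
  p1 <- cochleaR:::solve_system(sys)
  rot <- exp(1i * 0.7)
  sys$rhs <- sys$rhs * rot
  p2 <- cochleaR:::solve_system(sys)
  expect_lt(max(abs(p2 - rot * p1) / abs(p1)), 1e-12)
})

test_that("uniform-duct response matches the closed-form transmission line", {
  # independent oracle: constant-coefficient line with matched termination
  # supports a single decaying exponential p(x) = Us * Zc * exp(-gamma x)
  t_um <- 10; w_mm <- 0.2; A_mm2 <- 0.5
  E0 <- 5e4; beta0 <- 1e-5; Cpl <- 175; nu <- 0.4; rho <- 1000
  f <- 1000
  geom <- uniform_geom(dx = 0.0025, t_um = t_um, w_mm = w_mm, A_mm2 = A_mm2)
  mat <- const_mat(E0 = E0, beta0 = beta0)
  resp <- solve_harmonic(geom, mat, stim = stimulus_spec(frequencies_Hz = f),
                         plate_constant = Cpl)

  om <- 2 * pi * f
  t_m <- t_um * 1e-6; w_m <- w_mm * 1e-3; A_m2 <- A_mm2 * 1e-6
  K <- Cpl * E0 * t_m^3 / ((1 - nu^2) * w_m^4)
  m <- rho * t_m
  Zp <- (K * (1 + 1i * om * beta0) - om^2 * m) / (1i * om)
  Ah <- A_m2 / 2
  Zs <- 1i * om * rho / Ah
  Y <- w_m / Zp
  gamma <- sqrt(Zs * Y); if (Re(gamma) < 0) gamma <- -gamma
  Zc <- sqrt(Zs / Y); if (Re(Zc) < 0) Zc <- -Zc
  Us <- 1i * om * 1e-8 * 1e-6
  p_exact <- Us * Zc * exp(-gamma * geom$x * 1e-3)
  u_exact <- p_exact / (1i * om * Zp)

  rel_l2 <- sqrt(sum((abs(resp$u[, 1]) - abs(u_exact))^2) /
                   sum(abs(u_exact)^2))
  expect_lt(rel_l2, 0.05)
})

test_that("input power equals dissipated power", {
  geom <- coarse_geom(dx = 0.01)
  mat <- quiet_mat()
  pp <- partition_params(geom, mat)
  occ <- place_electrode(geom, electrode_spec(insertion_angle_deg = 540))
  for (f in c(400, 2000, 10000)) {
    for (o in list(NULL, occ)) {
      sys <- assemble_system(geom, pp, f = f, occ = o)
      p <- cochleaR:::solve_system(sys)
      pb <- power_balance(sys, p)
      expect_gt(pb$P_in, 0)
      expect_lt(pb$rel_err, 0.01)
    }
  }
})

test_that("solve diagnostics report tiny residuals and reject bad grids", {
  geom <- coarse_geom(dx = 0.05)
  mat <- quiet_mat()
  resp <- solve_harmonic(geom, mat)
  expect_true(all(resp$diagnostics$residual < 1e-8))
  expect_true(all(is.finite(resp$u)))

  other <- coarse_geom(dx = 0.1)
  pp_other <- partition_params(other, mat)
  expect_error(assemble_system(geom, pp_other, f = 1000), "grid")
  occ_other <- place_electrode(other, electrode_spec())
  pp <- partition_params(geom, mat)
  expect_error(assemble_system(geom, pp, f = 1000, occ = occ_other), "grid")
})

test_that("the acoustic formulation solves and stays close to incompressible", {
  geom <- coarse_geom(dx = 0.05)
  mat <- quiet_mat()
  stim <- stimulus_spec(frequencies_Hz = c(1000, 8000))
  ri <- solve_harmonic(geom, mat, stim = stim)
  ra <- solve_harmonic(geom, mat, stim = stim,
                       settings = solver_settings(formulation = "acoustic"))
  expect_true(all(is.finite(ra$u)))
  # compressibility is a small correction at cochlear dimensions
  pk_i <- apply(abs(ri$u), 2, max)
  pk_a <- apply(abs(ra$u), 2, max)
  expect_true(all(abs(pk_a / pk_i - 1) < 0.2))
})

test_that("stimulus and settings validation rejects bad values", {
  expect_error(stimulus_spec(frequencies_Hz = c(2000, 1000)), "sorted")
  expect_error(stimulus_spec(frequencies_Hz = -1), "positive")
  expect_error(stimulus_spec(stapes_displacement_m = c(1e-8, 1e-8)),
               "per frequency")
  expect_error(solver_settings(tolerance = 1e-3), "tolerance")
  expect_error(solver_settings(footplate_area_mm2 = 0), "positive")
})
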