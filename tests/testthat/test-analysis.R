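test_that("normalization divides by the recorded stapes displacement", {
  x <- seq(0, 1, by = 0.1)
  us <- c(1e-8, 2e-8)
  u <- cbind(rep(1e-8 + 0i, 11), rep(2e-8 + 0i, 11))
  resp <- fake_response(x, u, us, c(1000, 2000))
  nm <- normalize_response(resp)
  expect_equal(nm, matrix(1, 11, 2), ignore_attr = TRUE)

  bad <- fake_response(x, u, c(0, 1e-8), c(1000, 2000))
  expect_error(normalize_response(bad), "zero")

  # scaling the drive leaves the normalized profile unchanged
  geom <- coarse_geom(dx = 0.05)
  mat <- quiet_mat()
  n1 <- normalize_response(
    solve_harmonic(geom, mat, stim = stimulus_spec(frequencies_Hz = 2000)))
  n2 <- normalize_response(
    solve_harmonic(geom, mat, stim = stimulus_spec(frequencies_Hz = 2000,
                                                   stapes_displacement_m = 5e-8)))
  expect_lt(max(abs(n1 - n2) / n1), 1e-12)
})

test_that("moving-average smoothing has the exact textbook responses", {
  x <- seq(0, 18.3, by = 0.01)
  n <- length(x)
  # constants pass through
  expect_equal(smooth_profile(rep(3.7, n), x), rep(3.7, n))
  # a unit spike becomes a plateau of height 1/(2k+1)
  k <- floor(0.2 / (2 * 0.01))  # 10
  spike <- numeric(n); spike[800] <- 5
  sm <- smooth_profile(spike, x)
  expect_equal(sm[800], 5 / (2 * k + 1))
  expect_equal(sm[800 - k], 5 / (2 * k + 1))
  expect_identical(sm[800 + k + 1], 0)
  # a sampled cosine is attenuated by exactly the Dirichlet-kernel gain
  lambda <- 0.35
  prof <- cos(2 * pi * x / lambda)
  gain <- sin((2 * k + 1) * pi * 0.01 / lambda) /
    ((2 * k + 1) * sin(pi * 0.01 / lambda))
  sm <- smooth_profile(prof, x)
  interior <- (k + 1):(n - k)
  expect_equal(sm[interior], gain * prof[interior], tolerance = 1e-10)

  expect_error(smooth_profile(prof, x, window_mm = 0.005), "window")
})

test_that("peak finding locates bumps, breaks ties basally, flags zeros", {
  x <- seq(0, 18.3, by = 0.05)
  bump <- exp(-(x - 7)^2)
  pk <- find_peak(bump, x)
  expect_lt(abs(pk$x_max - 7), 0.05 + 1e-12)
  expect_false(pk$flagged)

  twin <- numeric(length(x))
  twin[c(100, 200)] <- 1
  expect_equal(find_peak(twin, x)$x_max, x[100])

  z <- find_peak(numeric(length(x)), x)
  expect_true(z$flagged)
  expect_true(is.na(z$x_max))
})

test_that("greenwood comparison round-trips and measures offsets", {
  map <- greenwood_map("chinchilla")
  L <- 18.3
  freqs <- c(400, 1000, 2000, 4000, 6000, 8000, 10000)
  gx <- greenwood_position(map, freqs, L)
  expect_true(all(is.finite(gx)))
  expect_true(all(diff(gx) < 0))  # higher frequencies map basally
  # frequencies at the map's own positions give zero error
  tun <- fake_tuning(freqs, gx, rep(1, 7), L = L)
  cmp <- compare_greenwood(tun, map)
  expect_equal(cmp$error_mm, rep(0, 7), tolerance = 1e-12)
  expect_equal(attr(cmp, "rms_mm"), 0, tolerance = 1e-12)
  # a constant offset comes back as exactly that RMS
  cmp2 <- compare_greenwood(fake_tuning(freqs, gx + 0.5, rep(1, 7), L = L),
                            map)
  expect_equal(attr(cmp2, "rms_mm"), 0.5)
  # out-of-range frequency is flagged as NA, not an error
  expect_true(is.na(greenwood_position(map, 5, L)))
  expect_true(is.na(greenwood_position(map, 1e6, L)))
})

test_that("the healthy default run lands near the Greenwood map", {
  res <- run_healthy(outdir = withr::local_tempdir())
  expect_lt(attr(res$tuning, "rms_mm"), 0.05 * 18.3)  # frozen regression bound
})

test_that("residual-hearing deltas are exact arithmetic on the tuning maps", {
  freqs <- c(1000, 4000)
  a <- fake_tuning(freqs, c(10, 6), c(100, 300))
  expect_identical(residual_hearing_delta(a, a)$dx_mm, c(0, 0))
  expect_identical(residual_hearing_delta(a, a)$ddB, c(0, 0))

  b <- fake_tuning(freqs, c(10, 6), c(200, 600), angle_deg = 540)
  d <- residual_hearing_delta(a, b)
  expect_equal(d$ddB, rep(20 * log10(2), 2))
  expect_identical(d$dx_mm, c(0, 0))
  expect_identical(d$angle_deg, c(540, 540))

  # antisymmetry
  cc <- fake_tuning(freqs, c(10.3, 5.9), c(150, 250))
  expect_equal(residual_hearing_delta(a, cc)$ddB,
               -residual_hearing_delta(cc, a)$ddB)
  expect_equal(residual_hearing_delta(a, cc)$dx_mm,
               -residual_hearing_delta(cc, a)$dx_mm)

  # mismatched configurations are refused with the field named
  mis <- fake_tuning(freqs, c(10, 6), c(100, 300), dx_mm = 0.02)
  expect_error(residual_hearing_delta(a, mis), "dx_mm")
  misf <- fake_tuning(c(1000, 8000), c(10, 6), c(100, 300))
  expect_error(residual_hearing_delta(a, misf), "frequencies")
})

test_that("tuning extraction reports one row per frequency with metadata", {
  geom <- coarse_geom(dx = 0.05)
  resp <- solve_harmonic(geom, quiet_mat(),
                         stim = stimulus_spec(frequencies_Hz = c(2000, 8000)))
  tun <- extract_tuning(resp)
  expect_s3_class(tun, "tuning_result")
  expect_identical(nrow(tun), 2L)
  expect_identical(attr(tun, "L"), 18.3)
  expect_false(any(tun$flagged))
  expect_true(all(tun$x_max_mm >= 0 & tun$x_max_mm <= 18.3))
})
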