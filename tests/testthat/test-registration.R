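# Rigid estimation, warping, LUT calibration, accuracy metrics.

test_that("analytic metrics: pixel pitch, error units, biased area", {
  expect_equal(pixel_pitch(2.5, 100), 25)
  expect_equal(pixel_pitch(1.0, 100), 10)
  expect_equal(pixel_pitch(2.5, 50), 50)
  expect_error(pixel_pitch(0, 100), ">")

  e <- transform_errors(rigid_transform(0.5, 1, 0), 25)
  expect_equal(e$translation_err_um, 25)
  expect_equal(e$rotation_err_arcmin, 30)
  e0 <- transform_errors(rigid_transform(), 25)
  expect_equal(c(e0$translation_err_um, e0$rotation_err_arcmin), c(0, 0))
  expect_error(transform_errors(rigid_transform(), -1), "pitch")

  expect_equal(biased_area_fraction(1, 25, "edge"), 0.04)
  expect_equal(biased_area_fraction(1, 25, "diagonal"),
               1 - (1 - 1 / (25 * sqrt(2)))^2)
  expect_equal(round(100 * biased_area_fraction(1, 25, "diagonal"), 1), 5.6)
  expect_equal(biased_area_fraction(0, 25, "edge"), 0)
  expect_error(biased_area_fraction(26, 25, "edge"), "t <= pitch")
})

test_that("intensity variation fraction uses an inclusive 0.25% bound", {
  ref <- matrix(1000, 10, 10)
  expect_equal(intensity_variation(ref, ref)$frac_within, 1)
  up <- ref + 0.003 * 65535
  expect_equal(intensity_variation(up, ref)$frac_within, 0)
  exact <- ref + 0.0025 * 65535
  expect_equal(intensity_variation(exact, ref)$frac_within, 1)
  expect_error(intensity_variation(ref, matrix(0, 5, 5)), "shape")
})

test_that("rigid transforms compose, invert and recenter consistently", {
  t1 <- rigid_transform(33, 4, -2, c(10, 20))
  pts <- cbind(runif(20, 0, 100), runif(20, 0, 100))
  fwd <- transform_points(t1, pts)
  back <- transform_points(invert_rigid(t1), fwd)
  expect_equal(back, pts, tolerance = 1e-12)
  t2 <- fibrojoint:::recenter_rigid(t1, c(50, 50))
  expect_equal(transform_points(t2, pts), fwd, tolerance = 1e-12)
  expect_error(rigid_transform(NaN, 0, 0), "finite")
})

test_that("estimate_rigid matches the closed-form Procrustes oracle", {
  set.seed(7)
  for (rep in 1:10) {
    a <- matrix(runif(60, 0, 100), 30, 2)
    theta <- runif(1, -170, 170)
    tv <- runif(2, -20, 20)
    b <- a %*% t(fibrojoint:::rot2(theta)) +
      matrix(tv, 30, 2, byrow = TRUE) +
      matrix(rnorm(60, sd = 0.3), 30, 2)
    pairs <- data.frame(xa = a[, 1], ya = a[, 2], xb = b[, 1], yb = b[, 2])
    est <- estimate_rigid(pairs, inlier_tol_px = 5, seed = rep)
    oracle <- procrustes_oracle(a, b)
    expect_equal(est$theta_deg, oracle$theta_deg, tolerance = 1e-9)
    expect_equal(est$tx_px, oracle$tx, tolerance = 1e-9)
    expect_equal(est$ty_px, oracle$ty, tolerance = 1e-9)
  }
})

test_that("RANSAC rejects gross outliers", {
  set.seed(8)
  a <- matrix(runif(100, 10, 90), 50, 2)
  b <- a %*% t(fibrojoint:::rot2(9)) + matrix(c(10, -5), 50, 2, byrow = TRUE)
  out <- sample(50, 10)
  b[out, ] <- b[out, ] + matrix(runif(20, 5, 30), 10, 2)
  pairs <- data.frame(xa = a[, 1], ya = a[, 2], xb = b[, 1], yb = b[, 2])
  est <- estimate_rigid(pairs, seed = 1)
  expect_lt(abs(est$theta_deg - 9), 0.01)
  expect_lt(abs(est$tx_px - 10), 0.05)
  expect_lt(abs(est$ty_px + 5), 0.05)
  expect_equal(sum(attr(est, "inliers")), 40)

  # identity on identical clouds; errors on degenerate input
  idp <- data.frame(xa = a[, 1], ya = a[, 2], xb = a[, 1], yb = a[, 2])
  estid <- estimate_rigid(idp, seed = 1)
  expect_equal(c(estid$theta_deg, estid$tx_px, estid$ty_px), c(0, 0, 0),
               tolerance = 1e-12)
  expect_error(estimate_rigid(pairs[1, ]), "2 matched pairs")
})

test_that("keypoint matching behaves on identical, rotated, flat images", {
  sc <- fixture_scene()
  img <- render_capture(sc, 0)
  pairs <- detect_and_match(img, img)
  expect_gte(nrow(pairs), 20)
  disp <- sqrt((pairs$xa - pairs$xb)^2 + (pairs$ya - pairs$yb)^2)
  expect_lt(max(disp), 1e-9)

  rot <- render_capture(sc, 9)
  pr <- detect_and_match(img, rot)
  est <- estimate_rigid(pr, seed = 1, center_px = c(50.5, 50.5))
  expect_lt(abs(est$theta_deg - 9), 0.2)
  expect_gt(mean(attr(est, "inliers")), 0.5)

  flat <- matrix(500, 100, 100)
  expect_equal(nrow(detect_and_match(flat, flat)), 0L)
})

test_that("apply_rigid is a faithful single-pass bicubic resampler", {
  sc <- fixture_scene()
  img <- render_capture(sc, 0)
  # identity is bit-identical
  out <- apply_rigid(img, rigid_transform())
  expect_identical(as.numeric(out), as.numeric(img))

  # half-pixel translation of a linear ramp shifts values by half a step
  ramp <- matrix(rep(seq(0, 990, by = 10), each = 50), 50, 100, byrow = FALSE)
  ramp <- ramp + 5  # avoid the zero fill confusing the interior check
  sh <- apply_rigid(ramp, rigid_transform(0, 0.5, 0))
  interior <- 10:40
  expect_equal(sh[interior, 20:80], ramp[interior, 20:80] - 5,
               tolerance = 1e-9, ignore_attr = TRUE)

  # rotation round trip on a smooth image
  smooth_sc <- make_bundle_scene(scene_config(blur_um = 25, rng_seed = 4L))
  simg <- render_capture(smooth_sc, 0)
  fwd <- apply_rigid(simg, rigid_transform(17, 0, 0, c(50.5, 50.5)))
  back <- apply_rigid(fwd, rigid_transform(-17, 0, 0, c(50.5, 50.5)))
  inner <- disk_mask(100, radius = 30)
  expect_lt(max(abs(back[inner] - simg[inner])) / 65535, 0.01)
  # mean intensity conserved for pure rotation of a smooth image
  expect_lt(abs(mean(fwd[inner]) / mean(simg[inner]) - 1), 0.001)

  expect_error(apply_rigid(img, rigid_transform(0, NA, 0)), "finite")
})

test_that("LUT calibration recovers the eccentric translation circle", {
  sc <- fixture_scene()
  cap <- capture_config(ecc_um = c(50, 0))
  angles <- seq(30, 345, by = 45)
  caps <- lapply(angles, function(a) render_capture(sc, a, cap))
  ref <- render_capture(sc, 0, cap)
  lut <- calibrate_lut(caps, ref, angles = angles, seed = 1)

  e <- lut$entries[lut$entries$motor_angle_deg > 0, ]
  t_um <- sqrt(e$tx_px^2 + e$ty_px^2) * sc$pitch_um
  chord <- 2 * 50 * sin(fibrojoint:::deg2rad(e$motor_angle_deg) / 2)
  expect_true(all(abs(t_um - chord) < 2))
  # theta tracks the motor angle (content rotates by -angle)
  expect_true(all(abs((e$theta_deg + e$motor_angle_deg) %% 360) < 0.2 |
                    abs(((e$theta_deg + e$motor_angle_deg) %% 360) - 360) < 0.2))

  ecc <- estimate_eccentricity(lut, sc$pitch_um)
  expect_lt(sqrt(sum((ecc - c(50, 0))^2)), 2)

  # identity at OREF
  at0 <- lut_offsets(lut, 0)
  expect_equal(c(at0$theta_deg, at0$tx_px, at0$ty_px), c(0, 0, 0))

  expect_error(calibrate_lut(caps[1:2], ref, angles = angles[1:2]),
               "at least 3")
  expect_error(calibrate_lut(list(matrix(1, 100, 100), matrix(1, 100, 100),
                                  matrix(1, 100, 100)),
                             ref, angles = c(10, 20, 30)),
               "calibration error")
})

test_that("LUT interpolation is exact at nodes, linear between, periodic", {
  entries <- data.frame(motor_angle_deg = c(0, 90, 180, 270),
                        theta_deg = c(0, -90, -180, -270),
                        tx_px = c(0, 2, 4, 2), ty_px = c(0, -1, 0, 1))
  lut <- registration_lut(entries, c(50.5, 50.5))
  at90 <- lut_offsets(lut, 90)
  expect_equal(c(at90$theta_deg, at90$tx_px, at90$ty_px), c(-90, 2, -1))
  mid <- lut_offsets(lut, 135)
  expect_equal(c(mid$theta_deg, mid$tx_px, mid$ty_px), c(-135, 3, -0.5))
  # wrap through 360/0: between 270 and 360 (= 0 with theta -360)
  wrap <- lut_offsets(lut, 315)
  expect_equal(wrap$theta_deg, -315)
  expect_equal(c(wrap$tx_px, wrap$ty_px), c(1, 0.5))
  expect_error(registration_lut(entries[0, ], c(50.5, 50.5)), "empty")
  expect_error(registration_lut(
    data.frame(motor_angle_deg = c(10, 10), theta_deg = 0, tx_px = 0,
               ty_px = 0), c(50, 50)), "increasing")
})

test_that("characterization reproduces the NM <= HR <= SR error ordering", {
  sc <- fixture_scene()
  cap <- capture_config(ecc_um = c(50, 20), noise_sd_counts = 60,
                        moire = c(0.23, 0.31, 0.7, 40))
  cfg <- motor_config(backlash_usteps = 2L)
  reps <- lapply(c(NM = "NM", HR = "HR", SR = "SR"), function(m)
    simulate_characterization(sc, cap, cfg, m, n_images = 8L, seed = 2))
  expect_lte(reps$NM$median_translation_um, reps$HR$median_translation_um)
  expect_lte(reps$HR$median_translation_um, reps$SR$median_translation_um)
  expect_gte(reps$NM$median_frac_within, reps$HR$median_frac_within)
  expect_gte(reps$HR$median_frac_within, reps$SR$median_frac_within)
  # SR rotation spread exceeds HR spread
  expect_gte(stats::IQR(reps$SR$rotation_err_arcmin),
             stats::IQR(reps$HR$rotation_err_arcmin))
  # determinism
  again <- simulate_characterization(sc, cap, cfg, "NM", n_images = 8L,
                                     seed = 2)
  expect_identical(again$translation_err_um, reps$NM$translation_err_um)
})
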