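# Ground-truth generators: scenes, captures, VSD sequences, IMU streams,
# trajectories.

test_that("bundle scene generation is deterministic and honors its config", {
  cfg <- scene_config(n_broken_patches = 2L, rng_seed = 42L)
  s1 <- make_bundle_scene(cfg)
  s2 <- make_bundle_scene(cfg)
  expect_identical(s1$img, s2$img)

  # exactly 2 near-zero patch blocks inside the field of view
  n <- nrow(s1$img)
  patch_px <- s1$cfg$oversample   # one patch per sensor pixel at defaults
  # count dark patches by block-averaging the central field
  field_px <- s1$cfg$sensor_px * s1$cfg$oversample
  i0 <- (n - field_px) / 2
  central <- s1$img[(i0 + 1):(i0 + field_px), (i0 + 1):(i0 + field_px)]
  blocks <- matrix(0, s1$cfg$sensor_px, s1$cfg$sensor_px)
  for (bi in seq_len(s1$cfg$sensor_px)) for (bj in seq_len(s1$cfg$sensor_px))
    blocks[bi, bj] <- mean(central[(bi - 1) * patch_px + seq_len(patch_px),
                                   (bj - 1) * patch_px + seq_len(patch_px)])
  expect_equal(sum(blocks < 0.02 * cfg$base_level), 2L)

  # zero base level scales the whole scene to zero
  dark <- make_bundle_scene(scene_config(base_level = 0))
  expect_true(all(dark$img == 0))

  expect_error(scene_config(sensor_px = 0), "sensor_px")
  expect_error(scene_config(n_broken_patches = 1e9), "n_broken_patches")
})

test_that("render_capture reproduces the eccentric-rotation geometry", {
  sc <- fixture_scene()
  # identity at angle 0 equals the plain downsampling of the scene center
  plain <- round(fibrojoint:::downsample_scene(sc))
  cap0 <- capture_config()
  expect_equal(as.numeric(render_capture(sc, 0, cap0)), as.numeric(plain))

  # rigid transform between two noiseless captures recovers the rotation
  cap <- capture_config(ecc_um = c(50, 0))
  fa <- render_capture(sc, 0, cap)
  fb <- render_capture(sc, 40, cap)
  pairs <- detect_and_match(fa, fb)
  expect_gt(nrow(pairs), 20)
  tr <- estimate_rigid(pairs, seed = 1, center_px = c(50.5, 50.5))
  expect_lt(abs(tr$theta_deg - 40), 0.1)

  # chord-length oracle: translation magnitude 2 |ecc| sin(phi/2)
  fc <- render_capture(sc, 90, cap)
  trc <- estimate_rigid(detect_and_match(fa, fc), seed = 1,
                        center_px = c(50.5, 50.5))
  t_um <- sqrt(trc$tx_px^2 + trc$ty_px^2) * sc$pitch_um
  expect_lt(abs(t_um - 2 * 50 * sin(pi / 4)), 1)

  # geometry error when the footprint exits the scene
  far <- capture_config(ecc_um = c(1200, 0))
  expect_error(render_capture(sc, 180, far), "geometry")
})

test_that("VSD sequences embed the prescribed bleach and wave", {
  sc <- fixture_scene(sensor_px = 40L, n_broken = 0L, seed = 5L)
  cfg <- vsd_sim_config(n_frames = 64L, dt_ms = 2, wave = NULL,
                        noise_sd = 0, bleach_coeffs = c(0.004, -0.03, 0.02),
                        preexposure_s = 1)
  v <- make_vsd_sequence(sc, cfg)
  expect_equal(dim(v$frames), c(64L, 40L, 40L))
  # noiseless, waveless: per-frame ratio to base equals 1 + bleach exactly
  ratios <- vapply(seq_len(64), function(t)
    mean(v$frames[t, , ] / v$base), numeric(1))
  expect_equal(ratios, 1 + v$bleach_gt, tolerance = 1e-12)
  # duration
  expect_equal(vsd_sim_config(n_frames = 512L, dt_ms = 2)$n_frames * 2 / 1000,
               1.024)
  # negative wave puts the ground-truth minimum inside the wave window
  cfgw <- vsd_sim_config(n_frames = 64L, dt_ms = 2,
                         wave = c(20, 20, 20, 1, -0.005, 5), noise_sd = 0)
  vw <- make_vsd_sequence(sc, cfgw)
  expect_equal(min(vw$wave_gt), -0.005, tolerance = 1e-6)
  expect_true(which.min(apply(vw$wave_gt, 1, min)) > 20)
})

test_that("IMU streams are consistent with the yaw profile", {
  imu <- make_imu_stream(function(t) rep(30, length(t)), 10,
                         imu_sim_config())
  expect_equal(nrow(imu), 500L)
  expect_true(all(abs(imu$gz) < 1e-9))
  expect_equal(imu$az, rep(1, 500))

  imu2 <- make_imu_stream(function(t) 90 * t, 2, imu_sim_config())
  expect_equal(imu2$gz, rep(90 * pi / 180, 100), tolerance = 1e-6)
  # magnetometer rotates with yaw
  expect_equal(sqrt(imu2$mx^2 + imu2$my^2), rep(25, 100), tolerance = 1e-9)

  expect_error(make_imu_stream(function(t) t, -1), "duration")
})

test_that("arena trajectories respect the arena and the turning bias", {
  cfg <- trajectory_config(duration_s = 60, frame_rate_hz = 100,
                           turning_bias = 36, rng_seed = 3L)
  tr <- make_arena_trajectory(cfg)
  expect_true(all(sqrt(tr$x_mm^2 + tr$y_mm^2) <= cfg$arena_radius_mm + 1e-9))
  expect_true(all(tr$conf >= 0 & tr$conf <= 1))
  expect_identical(tr, make_arena_trajectory(cfg))

  # net cumulated yaw approximates bias * duration (mean over seeds)
  nets <- vapply(1:5, function(s) {
    t2 <- make_arena_trajectory(
      trajectory_config(duration_s = 100, frame_rate_hz = 50,
                        turning_bias = 36, rng_seed = s))
    t2$yaw_deg[nrow(t2)] - t2$yaw_deg[1]
  }, numeric(1))
  expect_lt(abs(mean(nets) - 3600), 1000)
})

test_that("capture closure: warping with the true transform undoes rotation", {
  # optically blurred scene: interpolation error is meaningful only when the
  # content is resolved by the sensor sampling
  sc <- make_bundle_scene(scene_config(n_broken_patches = 2L, blur_um = 25,
                                       rng_seed = 11L))
  cap <- capture_config(ecc_um = c(50, 20))
  phi <- 25
  ref <- render_capture(sc, 0, cap)
  rot <- render_capture(sc, phi, cap)
  # true capture->reference map: rotation -phi about the axis at +ecc
  ecc_px <- cap$ecc_um / sc$pitch_um
  R <- fibrojoint:::rot2(-phi)
  tv <- drop((diag(2) - R) %*% ecc_px)
  tr <- rigid_transform(-phi, tv[1], tv[2], c(50.5, 50.5))
  back <- apply_rigid(rot, tr)
  inner <- disk_mask(100, radius = 35) & attr(back, "valid")
  expect_lt(max(abs(back[inner] - ref[inner])) / 65535, 0.01)
})
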