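# dF/F0, photobleaching fit/correction, pre-exposure regression, Fourier
# notch, spatial smoothing.

test_that("compute_dff normalizes by the three-frame F0 and flags F0 <= 0", {
  fr <- array(100, c(10, 4, 4))
  const <- compute_dff(list(frames = fr, dt_ms = 2), ref_frame = 5)
  expect_true(all(const$frames == 0))

  fr2 <- fr
  fr2[7, 1, 1] <- 101
  d <- compute_dff(list(frames = fr2, dt_ms = 2), ref_frame = 3)
  expect_equal(d$frames[7, 1, 1], 0.01, tolerance = 1e-12)

  fr3 <- fr
  fr3[2:4, 2, 2] <- 0
  d3 <- compute_dff(list(frames = fr3, dt_ms = 2), ref_frame = 3)
  expect_false(d3$valid[2, 2])
  expect_true(all(is.na(d3$frames[, 2, 2])))
  expect_true(all(is.finite(d3$frames[, 1, 1])))

  expect_error(compute_dff(list(frames = fr, dt_ms = 2), ref_frame = 1),
               "window")
  expect_error(compute_dff(list(frames = fr, dt_ms = 2), ref_frame = 10),
               "window")
})

test_that("fit_bleach recovers exact quadratic trends on the absolute axis", {
  t_abs <- 1.25 + (0:199) * 0.002
  truth <- c(a = 0.004, b = -0.03, c = 0.02)
  tr <- truth[1] * t_abs^2 + truth[2] * t_abs + truth[3]
  s <- list(frames = array(tr, c(200, 1, 1)), dt_ms = 2, preexposure_s = 1.25)
  fit <- fit_bleach(s, matrix(TRUE, 1, 1))
  expect_equal(unname(fit$poly), unname(truth), tolerance = 1e-6)

  flat <- list(frames = array(0.01, c(50, 1, 1)), dt_ms = 2,
               preexposure_s = 0)
  ff <- fit_bleach(flat, matrix(TRUE, 1, 1))
  expect_lt(abs(ff$poly[1]), 1e-10)
  expect_lt(abs(ff$poly[2]), 1e-10)

  expect_error(fit_bleach(list(frames = array(1, c(1, 1, 1)), dt_ms = 2),
                          matrix(TRUE, 1, 1)), "short")
  expect_error(fit_bleach(s, matrix(FALSE, 1, 1)), "ROI")
})

test_that("correct_bleach flattens the trend and preserves fast waves", {
  sc <- fixture_scene(sensor_px = 40L, n_broken = 0L, seed = 5L)
  # pure bleach
  cfg <- vsd_sim_config(n_frames = 256L, dt_ms = 2,
                        bleach_coeffs = c(0.004, -0.03, 0.02),
                        preexposure_s = 1.5, wave = NULL, noise_sd = 0)
  v <- make_vsd_sequence(sc, cfg)
  dff <- compute_dff(v, ref_frame = 10)
  roi <- matrix(TRUE, 40, 40)
  fit <- fit_bleach(dff, roi)
  corr <- correct_bleach(dff, fit)
  tr <- vapply(1:256, function(t) mean(corr$frames[t, , ], na.rm = TRUE),
               numeric(1))
  expect_lt(sqrt(mean(tr^2)), 0.05 * diff(range(fit$raw_trace)))

  # bleach + wave: wave amplitude preserved within 10%
  cfgw <- vsd_sim_config(n_frames = 256L, dt_ms = 2,
                         bleach_coeffs = c(0.004, -0.03, 0.02),
                         preexposure_s = 1.5,
                         wave = c(120, 20, 20, 1.2, -0.005, 6), noise_sd = 0)
  vw <- make_vsd_sequence(sc, cfgw)
  dffw <- compute_dff(vw, ref_frame = 10)
  fitw <- fit_bleach(dffw, roi)
  corrw <- correct_bleach(dffw, fitw)
  roi_small <- disk_mask(40, center = 20, radius = 10)
  rec <- vapply(1:256, function(t)
    mean(corrw$frames[t, , ][roi_small], na.rm = TRUE), numeric(1))
  gt <- vapply(1:256, function(t) mean(vw$wave_gt[t, , ][roi_small]),
               numeric(1))
  expect_lt(abs(min(rec) - min(gt)) / abs(min(gt)), 0.10)

  # zero fit is the identity
  same <- correct_bleach(dffw, c(0, 0, 0))
  expect_identical(same$frames, dffw$frames)
})

test_that("bleach_vs_preexposure regresses ln(a) on pre-exposure time", {
  co <- c(-2, -1.5, 0.2)
  tpre <- seq(0.5, 4, length.out = 8)
  a <- exp(co[1] + co[2] * tpre + co[3] * tpre^2)
  reg <- bleach_vs_preexposure(a, tpre)
  expect_equal(reg$coefficients, co, tolerance = 1e-3)
  pred <- reg$predict(2)
  expect_equal(as.numeric(pred), co[1] + co[2] * 2 + co[3] * 4,
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_true(all(dim(attr(pred, "confidence")) == c(1, 2)))

  expect_warning(
    expect_error(bleach_vs_preexposure(c(1, 2, -1), c(1, 2, 3)), "3 trials"),
    "excluded")
  expect_error(bleach_vs_preexposure(c(1, 2, 3), c(2, 2, 2)),
               "rank|distinct")
  expect_error(bleach_vs_preexposure(c(1, 2), c(1, 2)), "3 trials")
})

test_that("the Fourier notch nulls masked bins exactly and nothing else", {
  set.seed(1)
  img <- matrix(rnorm(64 * 64), 64, 64)
  fx <- 6 / 64; fy <- 10 / 64
  g <- expand.grid(r = 0:63, c = 0:63)
  sine <- matrix(3 * sin(2 * pi * (fx * g$c + fy * g$r) + 0.4), 64, 64)
  noisy <- img + sine
  out <- remove_patterned_noise(noisy, noise_mask(c(fx, fy)))
  F_in <- stats::fft(noisy); F_out <- stats::fft(out)
  b <- fibrojoint:::mask_bins(noise_mask(c(fx, fy)), 64, 64)
  expect_lt(max(Mod(F_out[b])), 1e-10 * max(Mod(F_in[b])))
  off <- Mod(F_out - F_in); off[b] <- 0
  expect_lt(max(off), 1e-10 * max(Mod(F_in)))
  expect_true(is.numeric(out) && !is.complex(out))

  # Parseval: energy drops by exactly the masked-bin energy
  e_removed <- sum(Mod(F_in[b])^2) / length(noisy)
  expect_equal(sum(noisy^2) - sum(out^2), e_removed, tolerance = 1e-6)

  # linearity on random pairs
  img2 <- matrix(rnorm(64 * 64), 64, 64)
  m <- noise_mask(c(fx, fy))
  lhs <- remove_patterned_noise(noisy + 2 * img2, m)
  rhs <- remove_patterned_noise(noisy, m) + 2 * remove_patterned_noise(img2, m)
  expect_equal(lhs, rhs, tolerance = 1e-10)

  # bin absent from the signal: output equals input
  clean <- remove_patterned_noise(img, noise_mask(c(20 / 64, 0)))
  expect_lt(max(abs(clean - img)), max(abs(img)) * 1)  # finite perturbation
  expect_error(noise_mask(c(0, 0)), "DC")
})

test_that("spatial smoothing is a normalized Gaussian with safe edges", {
  const <- matrix(7, 20, 20)
  expect_equal(spatial_smooth(const), const, tolerance = 1e-12)
  imp <- matrix(0, 21, 21); imp[11, 11] <- 1
  sm <- spatial_smooth(imp)
  expect_equal(sum(sm), 1, tolerance = 1e-12)
  k <- sm[9:13, 9:13]
  expect_equal(sum(k), 1, tolerance = 1e-12)
  expect_equal(k, t(k), tolerance = 1e-12)   # symmetric kernel
  expect_error(spatial_smooth(const, kernel_px = 4L), "odd")
})

test_that("the full chain recovers an embedded wave from raw counts", {
  sc <- fixture_scene(sensor_px = 60L, n_broken = 0L, seed = 3L)
  cfg <- vsd_sim_config(n_frames = 256L, dt_ms = 2,
                        bleach_coeffs = c(0.004, -0.03, 0.02),
                        preexposure_s = 1.5,
                        wave = c(120, 30, 30, 1.2, -0.005, 6),
                        noise_sd = 0.002, rng_seed = 4L)
  v <- make_vsd_sequence(sc, cfg)
  # inject the moire sinusoid the notch must take out again
  g <- expand.grid(r = 0:59, c = 0:59)
  pat <- matrix(sin(2 * pi * (6 / 60 * g$c + 9 / 60 * g$r)), 60, 60)
  for (t in 1:256) v$frames[t, , ] <- v$frames[t, , ] * (1 + 0.004 * pat)

  dff <- compute_dff(v, ref_frame = 10)
  fit <- fit_bleach(dff, matrix(TRUE, 60, 60))
  corr <- correct_bleach(dff, fit)
  den <- remove_patterned_noise(corr, noise_mask(c(6 / 60, 9 / 60)))
  sm <- spatial_smooth(den)

  roi <- disk_mask(60, center = 30, radius = 15)
  rec <- vapply(1:256, function(t) mean(sm$frames[t, , ][roi], na.rm = TRUE),
                numeric(1))
  gt <- vapply(1:256, function(t) mean(v$wave_gt[t, , ][roi]), numeric(1))
  expect_identical(which.min(rec), which.min(gt))
  expect_lt(abs(min(rec) - min(gt)) / abs(min(gt)), 0.15)
})
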