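# Synthetic inputs with known ground truth: fiber-bundle scenes, sensor
# captures under joint rotation, VSD sequences, IMU streams, arena
# trajectories.

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Scene configuration for the synthetic fiber-bundle field
#'
#' Describes the square fiber-bundle imaging field: a 2.5 x 2.5 mm surface of
#' 600 x 600 fibers assembled in 6 x 6-fiber patch elements, imaged on a
#' 100 x 100 pixel 16-bit sensor (25 um per pixel). The visible texture is the
#' patch mosaic (one patch per sensor pixel at the defaults); individual 8-um
#' fibers are below the sensor's sampling pitch and are not modeled.
#'
#' @param field_mm physical width of the square bundle field (mm).
#' @param sensor_px sensor pixels per side.
#' @param patch_grid number of 6x6-fiber patch elements per side of the field.
#' @param n_broken_patches number of dark (broken) patch elements placed
#'   inside the field of view.
#' @param vignette_strength radial intensity falloff, 0 (none) to 1.
#' @param base_level mean resting-fluorescence level in 16-bit counts.
#' @param patch_gain_sd log-normal sd of the per-patch gain (mosaic contrast).
#' @param patch_mod_depth depth (0-1) of the intra-patch dome profile that
#'   makes patch borders visibly darker.
#' @param oversample scene oversampling factor relative to the sensor pitch;
#'   kept >= 4 so sub-pixel rigid motion is well defined.
#' @param blur_um Gaussian optical blur (sigma, micrometers) applied to the
#'   scene, emulating the fiber-core/NA point spread; 0 keeps the raw patch
#'   mosaic with its sharp boundaries.
#' @param rng_seed integer seed; the scene is bit-reproducible given the seed.
#' @return a `scene_config` list.
#' @export
scene_config <- function(field_mm = 2.5, sensor_px = 100L, patch_grid = 100L,
                         n_broken_patches = 0L, vignette_strength = 0.15,
                         base_level = 30000, patch_gain_sd = 0.2,
                         patch_mod_depth = 0.35, oversample = 4L,
                         blur_um = 0, rng_seed = 1L) {
  check_scalar(blur_um, "blur_um", lower = 0)
  check_scalar(field_mm, "field_mm", lower = 1e-6)
  check_scalar(sensor_px, "sensor_px", lower = 1, integer = TRUE)
  check_scalar(patch_grid, "patch_grid", lower = 1, integer = TRUE)
  check_scalar(n_broken_patches, "n_broken_patches", lower = 0,
               upper = patch_grid^2, integer = TRUE)
  check_scalar(vignette_strength, "vignette_strength", lower = 0, upper = 1)
  check_scalar(base_level, "base_level", lower = 0, upper = 65535)
  check_scalar(patch_gain_sd, "patch_gain_sd", lower = 0)
  check_scalar(patch_mod_depth, "patch_mod_depth", lower = 0, upper = 1)
  check_scalar(oversample, "oversample", lower = 4, integer = TRUE)
  check_scalar(rng_seed, "rng_seed", integer = TRUE)
  structure(list(field_mm = field_mm, sensor_px = as.integer(sensor_px),
                 patch_grid = as.integer(patch_grid),
                 n_broken_patches = as.integer(n_broken_patches),
                 vignette_strength = vignette_strength,
                 base_level = base_level, patch_gain_sd = patch_gain_sd,
                 patch_mod_depth = patch_mod_depth,
                 oversample = as.integer(oversample), blur_um = blur_um,
                 rng_seed = as.integer(rng_seed)),
            class = "scene_config")
}

#' Generate an oversampled fiber-bundle scene
#'
#' Builds the continuous object that the sensor looks at: a patch-mosaic
#' texture (random per-patch gain, dome-shaped intra-patch profile), a radial
#' vignette, and `n_broken_patches` near-zero patch elements inside the field
#' of view. The scene extends 1.5x beyond the half-field so that the sensor
#' footprint stays inside it for any rotation angle and a modest rotation-axis
#' eccentricity.
#'
#' Coordinates: the scene matrix is indexed `[row, col]`; the bundle center is
#' at the matrix center; physical positions are in micrometers with x along
#' columns and y along rows.
#'
#' @param cfg a [scene_config()].
#' @return an `fj_scene` object: `img` (float matrix), `px_um` (scene pixel
#'   size), `pitch_um` (sensor pixel size), `half_ext_um` (scene half-extent),
#'   `field_um`, and `cfg`.
#' @export
make_bundle_scene <- function(cfg = scene_config()) {
  if (!inherits(cfg, "scene_config")) cfg <- do.call(scene_config, cfg)
  field_um <- cfg$field_mm * 1000
  pitch_um <- field_um / cfg$sensor_px
  px_um <- pitch_um / cfg$oversample
  half_ext_um <- field_um / 2 * 1.5
  n <- 2L * as.integer(round(half_ext_um / px_um))  # even size, center between pixels
  ax <- (seq_len(n) - (n + 1) / 2) * px_um          # um relative to bundle center

  patch_um <- field_um / cfg$patch_grid
  # patch index of each scene pixel (can be negative outside the field)
  pidx <- floor(ax / patch_um)
  prange <- range(pidx)
  np <- prange[2] - prange[1] + 1L

  scene <- with_seed(cfg$rng_seed, {
    gains <- matrix(exp(stats::rnorm(np * np, sd = cfg$patch_gain_sd)), np, np)
    # broken patches live strictly inside the field of view
    in_field <- seq(0L, cfg$patch_grid - 1L) - cfg$patch_grid %/% 2L
    if (cfg$n_broken_patches > 0L) {
      cells <- expand.grid(i = in_field, j = in_field)
      pick <- cells[sample.int(nrow(cells), cfg$n_broken_patches), ]
      gains[cbind(pick$i - prange[1] + 1L, pick$j - prange[1] + 1L)] <- 0.005
    }
    gi <- pidx - prange[1] + 1L
    gain_img <- gains[cbind(rep(gi, times = n), rep(gi, each = n))]
    dim(gain_img) <- c(n, n)

    u <- (ax / patch_um) %% 1
    dome <- 0.5 - 0.5 * cos(2 * pi * u)
    mod <- (1 - cfg$patch_mod_depth) +
      cfg$patch_mod_depth * outer(dome, dome)

    r2 <- outer(ax^2, ax^2, "+") / (field_um^2 / 2)  # 1 at field corner
    vig <- 1 - cfg$vignette_strength * pmin(r2, 1)

    img <- cfg$base_level * gain_img * mod * vig
    if (cfg$blur_um > 0) img <- gauss_blur(img, cfg$blur_um / px_um)
    img
  })

  structure(list(img = scene, px_um = px_um, pitch_um = pitch_um,
                 half_ext_um = half_ext_um, field_um = field_um, cfg = cfg),
            class = "fj_scene")
}

#' Capture configuration for the simulated sensor
#'
#' @param ecc_um 2-vector (x, y): offset of the joint's rotation axis from the
#'   sensor center, in micrometers. A non-zero offset makes the image content
#'   describe a circle of this radius as the motor rotates.
#' @param residual_rot_amp_deg amplitude of an optional angle-dependent
#'   rotation offset (sinusoid of the motor angle), default 0.
#' @param noise_sd_counts additive Gaussian sensor noise, sd in counts.
#' @param moire patterned-noise sinusoid `c(fx, fy, phase, amplitude)`:
#'   spatial frequencies in cycles/pixel, phase in radians, amplitude in
#'   counts. A single global 2-D sine, static in the sensor frame.
#' @param bit_depth sensor bit depth (frames are clipped and quantized).
#' @param subsamples sub-samples per pixel side for area-averaged sampling.
#' @param rng_seed integer seed for the noise, or NULL to use the current RNG.
#' @return a `capture_config` list.
#' @export
capture_config <- function(ecc_um = c(0, 0), residual_rot_amp_deg = 0,
                           noise_sd_counts = 0, moire = c(0, 0, 0, 0),
                           bit_depth = 16L, subsamples = 4L, rng_seed = NULL) {
  if (!is.numeric(ecc_um) || length(ecc_um) != 2L || any(!is.finite(ecc_um)))
    stop_config("ecc_um", "must be a finite 2-vector")
  check_scalar(residual_rot_amp_deg, "residual_rot_amp_deg")
  check_scalar(noise_sd_counts, "noise_sd_counts", lower = 0)
  if (!is.numeric(moire) || length(moire) != 4L || any(!is.finite(moire)))
    stop_config("moire", "must be c(fx, fy, phase, amplitude)")
  if (moire[4] < 0) stop_config("moire", "amplitude must be >= 0")
  check_scalar(bit_depth, "bit_depth", lower = 1, upper = 32, integer = TRUE)
  check_scalar(subsamples, "subsamples", lower = 1, integer = TRUE)
  if (!is.null(rng_seed)) check_scalar(rng_seed, "rng_seed", integer = TRUE)
  structure(list(ecc_um = as.numeric(ecc_um),
                 residual_rot_amp_deg = residual_rot_amp_deg,
                 noise_sd_counts = noise_sd_counts, moire = as.numeric(moire),
                 bit_depth = as.integer(bit_depth),
                 subsamples = as.integer(subsamples), rng_seed = rng_seed),
            class = "capture_config")
}

# Bilinear lookup of scene values at physical positions (um from bundle
# center). Errors if any position falls outside the scene.
scene_lookup <- function(scene, x_um, y_um) {
  n <- nrow(scene$img)
  # position -> fractional 1-based index: center between pixels (n+1)/2
  fx <- x_um / scene$px_um + (n + 1) / 2
  fy <- y_um / scene$px_um + (n + 1) / 2
  if (any(fx < 1 | fx > n | fy < 1 | fy > n))
    stop("geometry error: sensor footprint exits the scene bounds",
         call. = FALSE)
  j0 <- pmin(floor(fx), n - 1); i0 <- pmin(floor(fy), n - 1)
  dx <- fx - j0; dy <- fy - i0
  img <- scene$img
  v00 <- img[cbind(i0, j0)];     v01 <- img[cbind(i0, j0 + 1)]
  v10 <- img[cbind(i0 + 1, j0)]; v11 <- img[cbind(i0 + 1, j0 + 1)]
  (1 - dy) * ((1 - dx) * v00 + dx * v01) + dy * ((1 - dx) * v10 + dx * v11)
}

#' Render a sensor capture of the scene at a motor angle
#'
#' The bundle content is rotated by the motor angle about the joint's rotation
#' axis, which sits `ecc_um` away from the sensor center (the bundle center
#' coincides with the sensor center at angle 0). Each sensor pixel
#' area-averages `subsamples^2` scene lookups; patterned (moire) noise and
#' additive Gaussian noise are then applied, and the frame is clipped and
#' quantized to `bit_depth`.
#'
#' @param scene an `fj_scene` from [make_bundle_scene()].
#' @param motor_angle_deg joint rotation angle, degrees (counter-clockwise
#'   positive in the x-along-columns / y-along-rows frame).
#' @param cap a [capture_config()].
#' @param offset_um additional mechanical displacement of the image content
#'   on the sensor (x, y), micrometers — models post-motion settling error.
#' @param extra_rot_deg additional mechanical rotation offset, degrees.
#' @return a `sensor_px x sensor_px` numeric matrix of quantized counts, with
#'   attributes `motor_angle_deg` and `pitch_um`.
#' @export
render_capture <- function(scene, motor_angle_deg, cap = capture_config(),
                           offset_um = c(0, 0), extra_rot_deg = 0) {
  stopifnot(inherits(scene, "fj_scene"))
  check_scalar(motor_angle_deg, "motor_angle_deg")
  n <- scene$cfg$sensor_px
  s <- cap$subsamples
  pitch <- scene$pitch_um
  centers <- (seq_len(n) - (n + 1) / 2) * pitch
  off <- ((seq_len(s) - (s + 1) / 2) / s) * pitch
  xs <- rep(centers, each = s) + rep(off, times = n)   # length n*s
  phi <- motor_angle_deg +
    cap$residual_rot_amp_deg * sin(deg2rad(motor_angle_deg)) + extra_rot_deg
  Rinv <- rot2(-phi)
  ecc <- cap$ecc_um
  # sample grid (row-major over y then x), sensor frame, um from sensor center
  px <- rep(xs, times = n * s) - offset_um[1]
  py <- rep(xs, each = n * s) - offset_um[2]
  # scene coords: q = R(-phi) (p - ecc) + ecc
  qx <- Rinv[1, 1] * (px - ecc[1]) + Rinv[1, 2] * (py - ecc[2]) + ecc[1]
  qy <- Rinv[2, 1] * (px - ecc[1]) + Rinv[2, 2] * (py - ecc[2]) + ecc[2]
  vals <- scene_lookup(scene, qx, qy)
  dim(vals) <- c(s, n, s, n)           # (sub-x, x, sub-y, y)
  frame <- apply(vals, c(4, 2), mean)  # -> [row(y), col(x)]

  if (cap$moire[4] > 0) {
    col_ix <- seq_len(n) - 1L; row_ix <- seq_len(n) - 1L
    ph <- 2 * pi * (outer(row_ix * cap$moire[2], col_ix * cap$moire[1], "+")) +
      cap$moire[3]
    frame <- frame + cap$moire[4] * sin(ph)
  }
  if (cap$noise_sd_counts > 0) {
    noise <- with_seed(cap$rng_seed,
                       matrix(stats::rnorm(n * n, sd = cap$noise_sd_counts),
                              n, n))
    frame <- frame + noise
  }
  maxv <- 2^cap$bit_depth - 1
  frame <- round(pmin(pmax(frame, 0), maxv))
  attr(frame, "motor_angle_deg") <- motor_angle_deg
  attr(frame, "pitch_um") <- pitch
  frame
}

# Area-averaged downsampling of the scene center to the sensor grid, no
# rotation, no noise, float output (used as the VSD base frame).
downsample_scene <- function(scene, subsamples = 4L) {
  cap <- capture_config(subsamples = subsamples)
  n <- scene$cfg$sensor_px
  s <- cap$subsamples
  pitch <- scene$pitch_um
  centers <- (seq_len(n) - (n + 1) / 2) * pitch
  off <- ((seq_len(s) - (s + 1) / 2) / s) * pitch
  xs <- rep(centers, each = s) + rep(off, times = n)
  px <- rep(xs, times = n * s)
  py <- rep(xs, each = n * s)
  vals <- scene_lookup(scene, px, py)
  dim(vals) <- c(s, n, s, n)
  apply(vals, c(4, 2), mean)
}

#' VSD sequence simulation configuration
#'
#' Models a voltage-sensitive-dye acquisition: `n_frames` frames at `dt_ms`
#' sampling (512 frames at 2 ms by default, about 1 s), multiplicative
#' photobleaching following a quadratic decay in dF/F units evaluated on the
#' absolute time axis (shutter opens `preexposure_s` before frame 0), an
#' optional embedded depolarization wave expanding from an origin, and
#' per-pixel Gaussian dF/F noise.
#'
#' @param n_frames number of frames.
#' @param dt_ms frame interval in milliseconds.
#' @param bleach_coeffs `c(a, b, c)` of the quadratic bleach trend
#'   `a t^2 + b t + c` (dF/F units, t in seconds of absolute exposure time).
#' @param preexposure_s shutter-open lead time before frame 0 (s).
#' @param wave `c(onset_frame, origin_row, origin_col, speed_px_per_frame,
#'   amplitude_dff, width_px)` or NULL for no wave. The wave is an expanding
#'   Gaussian annulus; amplitude may be negative or positive.
#' @param noise_sd per-pixel dF/F noise sd.
#' @param rng_seed integer seed.
#' @return a `vsd_sim_config` list.
#' @export
vsd_sim_config <- function(n_frames = 512L, dt_ms = 2,
                           bleach_coeffs = c(0.004, -0.02, 0.01),
                           preexposure_s = 1.5,
                           wave = c(150, 50, 50, 1.5, -0.005, 8),
                           noise_sd = 0, rng_seed = 1L) {
  check_scalar(n_frames, "n_frames", lower = 1, integer = TRUE)
  check_scalar(dt_ms, "dt_ms", lower = 1e-9)
  if (!is.numeric(bleach_coeffs) || length(bleach_coeffs) != 3L)
    stop_config("bleach_coeffs", "must be c(a, b, c)")
  check_scalar(preexposure_s, "preexposure_s", lower = 0)
  if (!is.null(wave)) {
    if (!is.numeric(wave) || length(wave) != 6L || any(!is.finite(wave)))
      stop_config("wave", paste0("must be c(onset_frame, origin_row, ",
                                 "origin_col, speed, amplitude, width)"))
    if (wave[6] <= 0) stop_config("wave", "width must be > 0")
  }
  check_scalar(noise_sd, "noise_sd", lower = 0)
  check_scalar(rng_seed, "rng_seed", integer = TRUE)
  structure(list(n_frames = as.integer(n_frames), dt_ms = dt_ms,
                 bleach_coeffs = as.numeric(bleach_coeffs),
                 preexposure_s = preexposure_s, wave = wave,
                 noise_sd = noise_sd, rng_seed = as.integer(rng_seed)),
            class = "vsd_sim_config")
}

#' Simulate a VSD image sequence with ground truth
#'
#' Frame `t` is `base * (1 + bleach(t) + wave(t) + noise)`, where `base` is
#' the area-averaged scene at the reference orientation and `bleach` is
#' evaluated at absolute time `preexposure_s + t * dt_ms`. Frames are kept in
#' floating point (quantization belongs to the capture path, not the dye
#' model).
#'
#' @param scene an `fj_scene`.
#' @param cfg a [vsd_sim_config()].
#' @return an `fj_vsd` object: `frames` (T x H x W array of counts), `dt_ms`,
#'   `preexposure_s`, `base` (H x W), `bleach_gt` (length-T dF/F trend),
#'   `wave_gt` (T x H x W dF/F ground-truth wave field), `cfg`.
#' @export
make_vsd_sequence <- function(scene, cfg = vsd_sim_config()) {
  stopifnot(inherits(scene, "fj_scene"))
  if (!inherits(cfg, "vsd_sim_config")) cfg <- do.call(vsd_sim_config, cfg)
  base <- downsample_scene(scene)
  h <- nrow(base); w <- ncol(base); T <- cfg$n_frames
  t_abs <- cfg$preexposure_s + (seq_len(T) - 1L) * cfg$dt_ms / 1000
  a <- cfg$bleach_coeffs
  bleach <- a[1] * t_abs^2 + a[2] * t_abs + a[3]

  wave_gt <- array(0, dim = c(T, h, w))
  if (!is.null(cfg$wave)) {
    onset <- cfg$wave[1]; o_r <- cfg$wave[2]; o_c <- cfg$wave[3]
    speed <- cfg$wave[4]; amp <- cfg$wave[5]; width <- cfg$wave[6]
    r <- sqrt(outer((seq_len(h) - o_r)^2, (seq_len(w) - o_c)^2, "+"))
    for (t in seq_len(T)) {
      if (t - 1L >= onset) {
        rho <- speed * (t - 1L - onset)
        wave_gt[t, , ] <- amp * exp(-(r - rho)^2 / (2 * width^2))
      }
    }
  }

  frames <- array(0, dim = c(T, h, w))
  noise <- if (cfg$noise_sd > 0)
    with_seed(cfg$rng_seed,
              array(stats::rnorm(T * h * w, sd = cfg$noise_sd), c(T, h, w)))
  else NULL
  for (t in seq_len(T)) {
    mod <- 1 + bleach[t] + wave_gt[t, , ]
    if (!is.null(noise)) mod <- mod + noise[t, , ]
    frames[t, , ] <- base * mod
  }
  structure(list(frames = frames, dt_ms = cfg$dt_ms,
                 preexposure_s = cfg$preexposure_s, base = base,
                 bleach_gt = bleach, wave_gt = wave_gt, cfg = cfg),
            class = "fj_vsd")
}

#' IMU stream simulation configuration
#'
#' @param rate_hz sampling rate (50 Hz matches the head-mounted sensor).
#' @param gyro_noise_sd gyroscope noise sd, rad/s.
#' @param accel_noise_sd accelerometer noise sd, g.
#' @param mag_noise_sd magnetometer noise sd, uT.
#' @param gyro_bias constant z-gyro bias, rad/s.
#' @param mag_field world-frame reference magnetic field, uT (x north, z up;
#'   the default has a typical mid-latitude inclination).
#' @param rng_seed integer seed.
#' @return an `imu_sim_config` list.
#' @export
imu_sim_config <- function(rate_hz = 50, gyro_noise_sd = 0,
                           accel_noise_sd = 0, mag_noise_sd = 0,
                           gyro_bias = 0, mag_field = c(25, 0, -40),
                           rng_seed = 1L) {
  check_scalar(rate_hz, "rate_hz", lower = 1e-9)
  check_scalar(gyro_noise_sd, "gyro_noise_sd", lower = 0)
  check_scalar(accel_noise_sd, "accel_noise_sd", lower = 0)
  check_scalar(mag_noise_sd, "mag_noise_sd", lower = 0)
  check_scalar(gyro_bias, "gyro_bias")
  if (!is.numeric(mag_field) || length(mag_field) != 3L)
    stop_config("mag_field", "must be a 3-vector")
  if (sqrt(sum(mag_field[1:2]^2)) < 1e-9)
    stop_config("mag_field", "needs a horizontal component for yaw sensing")
  check_scalar(rng_seed, "rng_seed", integer = TRUE)
  structure(list(rate_hz = rate_hz, gyro_noise_sd = gyro_noise_sd,
                 accel_noise_sd = accel_noise_sd, mag_noise_sd = mag_noise_sd,
                 gyro_bias = gyro_bias, mag_field = as.numeric(mag_field),
                 rng_seed = as.integer(rng_seed)),
            class = "imu_sim_config")
}

#' Synthesize a 9-DoF IMU stream consistent with a yaw profile
#'
#' The animal sits on a horizontal floor: gravity is (0, 0, 1) g in the world
#' frame and the head rotates about the world z-axis only. The noiseless
#' z-gyro equals the yaw rate (rad/s), the accelerometer reads gravity in the
#' sensor frame, and the magnetometer reads the reference field rotated into
#' the sensor frame.
#'
#' @param yaw_profile function mapping time (s, vectorized) to yaw (degrees).
#' @param duration_s stream duration, seconds (> 0).
#' @param cfg an [imu_sim_config()].
#' @return a data frame with columns `t_s, gx, gy, gz, ax, ay, az, mx, my, mz`
#'   (gyro rad/s, accel g, mag uT).
#' @export
make_imu_stream <- function(yaw_profile, duration_s,
                            cfg = imu_sim_config()) {
  stopifnot(is.function(yaw_profile))
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("duration_s must be > 0", call. = FALSE)
  if (!inherits(cfg, "imu_sim_config")) cfg <- do.call(imu_sim_config, cfg)
  n <- round(duration_s * cfg$rate_hz)
  t <- (seq_len(n) - 1L) / cfg$rate_hz
  yaw <- vapply(t, yaw_profile, numeric(1))
  h <- 1e-4
  rate_dps <- (vapply(t + h, yaw_profile, numeric(1)) -
                 vapply(t - h, yaw_profile, numeric(1))) / (2 * h)
  yr <- deg2rad(yaw)
  cy <- cos(yr); sy <- sin(yr)
  m <- cfg$mag_field
  # body measurement of a world vector: R_z(-yaw) %*% v
  mx <- cy * m[1] + sy * m[2]
  my <- -sy * m[1] + cy * m[2]
  mz <- rep(m[3], n)
  out <- data.frame(
    t_s = t,
    gx = 0, gy = 0, gz = deg2rad(rate_dps) + cfg$gyro_bias,
    ax = 0, ay = 0, az = 1,
    mx = mx, my = my, mz = mz)
  if (cfg$gyro_noise_sd > 0 || cfg$accel_noise_sd > 0 ||
      cfg$mag_noise_sd > 0) {
    out <- with_seed(cfg$rng_seed, {
      for (col in c("gx", "gy", "gz"))
        out[[col]] <- out[[col]] + stats::rnorm(n, sd = cfg$gyro_noise_sd)
      for (col in c("ax", "ay", "az"))
        out[[col]] <- out[[col]] + stats::rnorm(n, sd = cfg$accel_noise_sd)
      for (col in c("mx", "my", "mz"))
        out[[col]] <- out[[col]] + stats::rnorm(n, sd = cfg$mag_noise_sd)
      out
    })
  }
  out
}

#' Arena trajectory simulation configuration
#'
#' @param arena_radius_mm radius of the circular open-field arena (150 mm for
#'   the 30-cm arena).
#' @param duration_s session duration, seconds.
#' @param frame_rate_hz tracking frame rate (500 Hz for the overhead camera).
#' @param speed_scale locomotion speed, mm/s.
#' @param turning_bias mean signed turning rate, deg/s (0 = unbiased walk).
#' @param turn_rate_sd stationary sd of the turning rate around the bias,
#'   deg/s (the rate follows a smooth mean-reverting process, so the head
#'   yaw is differentiable and angular-velocity metrics stay frame-rate
#'   independent).
#' @param turn_tau_s relaxation time of the turning-rate process, s.
#' @param rng_seed integer seed.
#' @return a `trajectory_config` list.
#' @export
trajectory_config <- function(arena_radius_mm = 150, duration_s = 60,
                              frame_rate_hz = 500, speed_scale = 50,
                              turning_bias = 0, turn_rate_sd = 45,
                              turn_tau_s = 1, rng_seed = 1L) {
  check_scalar(arena_radius_mm, "arena_radius_mm", lower = 1e-9)
  check_scalar(duration_s, "duration_s", lower = 1e-9)
  check_scalar(frame_rate_hz, "frame_rate_hz", lower = 1e-9)
  check_scalar(speed_scale, "speed_scale", lower = 1e-9)
  check_scalar(turning_bias, "turning_bias")
  check_scalar(turn_rate_sd, "turn_rate_sd", lower = 0)
  check_scalar(turn_tau_s, "turn_tau_s", lower = 1e-9)
  check_scalar(rng_seed, "rng_seed", integer = TRUE)
  structure(list(arena_radius_mm = arena_radius_mm, duration_s = duration_s,
                 frame_rate_hz = frame_rate_hz, speed_scale = speed_scale,
                 turning_bias = turning_bias, turn_rate_sd = turn_rate_sd,
                 turn_tau_s = turn_tau_s, rng_seed = as.integer(rng_seed)),
            class = "trajectory_config")
}

#' Simulate a tracked open-field trajectory
#'
#' The turning rate follows a mean-reverting (Ornstein-Uhlenbeck) process
#' around `turning_bias`, so the heading is smooth and angular-velocity
#' metrics do not depend on the tracking frame rate; the animal advances at
#' `speed_scale` mm/s. At the arena wall the position is clamped to the
#' radius (the animal slides along the wall) while the heading continues its
#' process, so the cumulated yaw reflects the generative turning model.
#' Confidence is near 1 with occasional low-confidence dropouts emulating
#' lost tracking markers.
#'
#' @param cfg a [trajectory_config()].
#' @return a data frame `t_s, x_mm, y_mm, conf, yaw_deg` (yaw unwrapped).
#' @export
make_arena_trajectory <- function(cfg = trajectory_config()) {
  if (!inherits(cfg, "trajectory_config")) cfg <- do.call(trajectory_config, cfg)
  n <- round(cfg$duration_s * cfg$frame_rate_hz)
  dt <- 1 / cfg$frame_rate_hz
  with_seed(cfg$rng_seed, {
    # OU turning rate: stationary sd turn_rate_sd, relaxation turn_tau_s
    alpha <- exp(-dt / cfg$turn_tau_s)
    innov_sd <- cfg$turn_rate_sd * sqrt(1 - alpha^2)
    rate <- numeric(n)
    rate[1] <- cfg$turning_bias + stats::rnorm(1, sd = cfg$turn_rate_sd)
    eps <- stats::rnorm(n - 1L, sd = innov_sd)
    for (k in 2:n)
      rate[k] <- cfg$turning_bias + alpha * (rate[k - 1] - cfg$turning_bias) +
        eps[k - 1]
    heading <- cumsum(c(stats::runif(1, -180, 180), rate[-1] * dt))
    step <- cfg$speed_scale * dt
    dx <- step * cos(deg2rad(heading))
    dy <- step * sin(deg2rad(heading))
    x <- numeric(n); y <- numeric(n)
    # start near the center
    x[1] <- stats::runif(1, -0.2, 0.2) * cfg$arena_radius_mm
    y[1] <- stats::runif(1, -0.2, 0.2) * cfg$arena_radius_mm
    R <- cfg$arena_radius_mm
    for (k in 2:n) {
      xn <- x[k - 1] + dx[k - 1]; yn <- y[k - 1] + dy[k - 1]
      r <- sqrt(xn^2 + yn^2)
      if (r > R) { xn <- xn * R / r; yn <- yn * R / r }
      x[k] <- xn; y[k] <- yn
    }
    conf <- pmin(1, pmax(0, 1 - abs(stats::rnorm(n, sd = 0.02))))
    drop <- stats::runif(n) < 0.01
    conf[drop] <- stats::runif(sum(drop), 0, 0.5)
    data.frame(t_s = (seq_len(n) - 1L) * dt, x_mm = x, y_mm = y,
               conf = conf, yaw_deg = heading)
  })
}
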