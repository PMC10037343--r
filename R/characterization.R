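# Simulated registration-accuracy characterization: the NM / HR / SR image
# series protocol, measured against a reference capture at OREF.

#' Simulate the optomechanical characterization protocol
#'
#' Reproduces, on the simulated bench, the three image-series conditions used
#' to characterize registration accuracy:
#'
#' * `NM` (no movement): repeated captures at OREF without moving the joint —
#'   the optical noise floor.
#' * `HR` (hardware registration): the joint cycles to a random orientation
#'   and locks back at OREF (anti-backlash approach) before every capture;
#'   a small post-motion settling jitter models residual mechanical error.
#' * `SR` (software registration): captures at orientations spanning the
#'   angle range, positioned with backlash from alternating directions, and
#'   registered offline via the motor-angle LUT with one-step bicubic
#'   resampling.
#'
#' Each test image is compared to the reference by keypoint matching and
#' robust rigid estimation; the report carries per-image translation (um) and
#' rotation (arcmin) errors and the fraction of pixels within +/-0.25% of the
#' full intensity range, evaluated on a central disk common to all modes.
#'
#' @param scene an `fj_scene`.
#' @param cap a [capture_config()] (noise, eccentricity, moire).
#' @param cfg a [motor_config()] (backlash, anti-backlash approach).
#' @param mode `"NM"`, `"HR"` or `"SR"`.
#' @param n_images images per series (25 in the hardware protocol).
#' @param angle_range orientations visited between/at captures, degrees.
#' @param seed integer seed; a fixed seed reproduces the report exactly.
#' @param lut optional pre-calibrated [registration_lut()] for SR; when NULL
#'   an LUT is calibrated from captures at `lut_angles`.
#' @param lut_angles calibration angles used when `lut` is NULL.
#' @param settle_um sd of the post-motion settling translation jitter
#'   (micrometers per axis), applied after any lock/positioning move.
#' @param settle_arcmin sd of the post-motion rotation jitter (arcmin).
#' @param oref_deg reference orientation.
#' @return an `accuracy_report`: per-image `translation_err_um`,
#'   `rotation_err_arcmin`, `frac_within_quarter_pct`, their medians, and
#'   protocol metadata (including the LUT used for SR).
#' @export
simulate_characterization <- function(scene, cap = capture_config(),
                                      cfg = motor_config(),
                                      mode = c("NM", "HR", "SR"),
                                      n_images = 25L,
                                      angle_range = c(9, 345), seed = 1L,
                                      lut = NULL,
                                      lut_angles = seq(15, 345, by = 30),
                                      settle_um = 0.3, settle_arcmin = 0.3,
                                      oref_deg = 0) {
  mode <- match.arg(mode)
  check_scalar(n_images, "n_images", lower = 1, integer = TRUE)
  pitch <- scene$pitch_um
  full_range <- 2^cap$bit_depth - 1
  n <- scene$cfg$sensor_px
  center <- c((n + 1) / 2, (n + 1) / 2)
  # central disk shared by all modes (stays valid under re-rotation)
  gx <- matrix(rep(seq_len(n), each = n), n, n)
  gy <- matrix(rep(seq_len(n), times = n), n, n)
  disk <- (gx - center[1])^2 + (gy - center[2])^2 <= (n / 2 - 10)^2

  with_seed(seed, {
    reference <- render_capture(scene, oref_deg, cap)
    ref_prep <- kp_prepare(reference)

    if (mode == "SR" && is.null(lut)) {
      calib <- lapply(lut_angles, function(a) render_capture(scene, a, cap))
      lut <- calibrate_lut(calib, reference, angles = lut_angles,
                           oref_deg = oref_deg)
    }

    spr <- steps_per_revolution(cfg)
    st <- joint_state(commanded_usteps = round(oref_deg * spr / 360),
                      output_usteps = round(oref_deg * spr / 360),
                      oref_usteps = round(oref_deg * spr / 360))
    sr_angles <- seq(angle_range[1], angle_range[2], length.out = n_images)

    trans_err <- numeric(n_images)
    rot_err <- numeric(n_images)
    frac <- numeric(n_images)

    for (i in seq_len(n_images)) {
      jitter_t <- stats::rnorm(2, sd = settle_um)
      jitter_r <- stats::rnorm(1, sd = settle_arcmin / 60)
      if (mode == "NM") {
        test <- render_capture(scene, oref_deg, cap)
        eval_img <- test
      } else if (mode == "HR") {
        # excursion to a random orientation, then anti-backlash lock at OREF
        away <- stats::runif(1, angle_range[1], angle_range[2]) *
          sample(c(-1, 1), 1)
        st <- unlock(st)
        st <- command_move(st, round(away * spr / 360), cfg)
        st <- lock_at_oref(st, cfg)
        test <- render_capture(scene, output_deg(st, cfg), cap,
                               offset_um = jitter_t,
                               extra_rot_deg = jitter_r)
        eval_img <- test
      } else {
        # position at the target angle, approaching from a random direction
        target <- round(sr_angles[i] * spr / 360)
        approach_dir <- sample(c(-1, 1), 1)
        st <- command_move(st, target - approach_dir * 40 -
                             st$commanded_usteps, cfg)
        st <- command_move(st, approach_dir * 40, cfg)
        test <- render_capture(scene, output_deg(st, cfg), cap,
                               offset_um = jitter_t,
                               extra_rot_deg = jitter_r)
        eval_img <- apply_rigid(test, lut_offsets(lut, sr_angles[i]))
      }
      pairs <- kp_match(kp_prepare(eval_img), ref_prep)
      t_res <- estimate_rigid(pairs, center_px = center)
      errs <- transform_errors(t_res, pitch)
      trans_err[i] <- errs$translation_err_um
      rot_err[i] <- errs$rotation_err_arcmin
      m <- disk
      v <- attr(eval_img, "valid")
      if (!is.null(v)) m <- m & v
      delta <- (eval_img[m] - reference[m]) / full_range * 100
      frac[i] <- mean(abs(delta) <= 0.25)
    }

    structure(list(mode = mode, n_images = n_images,
                   translation_err_um = trans_err,
                   rotation_err_arcmin = rot_err,
                   median_translation_um = stats::median(trans_err),
                   median_rotation_arcmin = stats::median(rot_err),
                   frac_within_quarter_pct = frac,
                   median_frac_within = stats::median(frac),
                   pixel_pitch_um = pitch, lut = lut, seed = seed),
              class = "accuracy_report")
  })
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf(
    paste0("%s characterization (%d images): median translation %.3f um, ",
           "median rotation %.3f arcmin, median frac within 0.25%%: %.1f%%\n"),
    x$mode, x$n_images, x$median_translation_um, x$median_rotation_arcmin,
    100 * x$median_frac_within))
  invisible(x)
}
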