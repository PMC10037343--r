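#!/usr/bin/env Rscript
# Thin command-line front end over the fibrojoint package.
#
#   fibrojoint <command> [--key value ...]
#
# Commands:
#   simulate-session  --mode HR|SR|HYBRID --duration 30 --seed 1 --out DIR
#   calibrate-lut     --seed 1 --ecc-x 50 --ecc-y 0 --out lut.csv
#   register          --stack in.tif --lut lut.csv --out out.tif
#   characterize      --mode NM|HR|SR --n 25 --seed 1 --out report.json
#   process-vsd       --stack in.tif --out DIR
#   behavior-metrics  --traj traj.csv --out metrics.json

suppressMessages(library(fibrojoint))

`%||%` <- function(a, b) if (is.null(a)) b else a

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L) {
  message("usage: fibrojoint <command> [--key value ...]; see script header")
  quit(status = 1)
}
cmd <- args[[1]]
kv <- list()
i <- 2L
while (i <= length(args)) {
  key <- sub("^--", "", args[[i]])
  kv[[key]] <- if (i + 1L <= length(args)) args[[i + 1L]] else ""
  i <- i + 2L
}
opt <- function(name, default = NULL) {
  v <- kv[[name]]
  if (is.null(v)) {
    if (is.null(default)) stop("missing required option --", name,
                               call. = FALSE)
    default
  } else v
}
num <- function(name, default = NULL) as.numeric(opt(name, default))
seed <- as.integer(num("seed", 1))
logmsg <- function(...) message(sprintf("[fibrojoint seed=%d] ", seed), ...)

status <- tryCatch({
  if (cmd == "characterize") {
    scene <- make_bundle_scene(scene_config(n_broken_patches = 3L,
                                            rng_seed = seed))
    rep <- simulate_characterization(
      scene,
      capture_config(ecc_um = c(50, 20), noise_sd_counts = 60,
                     moire = c(0.23, 0.31, 0.7, 40)),
      motor_config(backlash_usteps = 2L),
      mode = opt("mode", "HR"), n_images = as.integer(num("n", 25)),
      seed = seed)
    out <- opt("out", "report.json")
    jsonlite::write_json(rep[c("mode", "n_images", "translation_err_um",
                               "rotation_err_arcmin",
                               "median_translation_um",
                               "median_rotation_arcmin",
                               "frac_within_quarter_pct",
                               "median_frac_within", "pixel_pitch_um")],
                         out, auto_unbox = TRUE, digits = NA)
    logmsg("report written to ", out)
  } else if (cmd == "calibrate-lut") {
    scene <- make_bundle_scene(scene_config(n_broken_patches = 3L,
                                            rng_seed = seed))
    cap <- capture_config(ecc_um = c(num("ecc-x", 50), num("ecc-y", 0)))
    angles <- seq(15, 345, by = 30)
    caps <- lapply(angles, function(a) render_capture(scene, a, cap))
    lut <- calibrate_lut(caps, render_capture(scene, 0, cap),
                         angles = angles, seed = seed)
    write_lut_csv(lut, opt("out", "lut.csv"))
    logmsg("LUT with ", nrow(lut$entries), " entries written")
  } else if (cmd == "register") {
    st <- read_stack(opt("stack"))
    lut <- read_lut_csv(opt("lut"))
    if (is.null(st$motor_angle_deg))
      stop("stack sidecar has no per-frame motor angles")
    reg <- st$frames
    for (t in seq_len(dim(reg)[1]))
      reg[t, , ] <- apply_rigid(st$frames[t, , ],
                                lut_offsets(lut, st$motor_angle_deg[t]))
    write_stack(pmin(pmax(reg, 0), 65535), opt("out"),
                motor_angle_deg = rep(lut$oref_deg, dim(reg)[1]),
                dt_ms = st$dt_ms)
    logmsg("registered ", dim(reg)[1], " frames")
  } else if (cmd == "simulate-session") {
    mode <- opt("mode", "HR")
    dur <- num("duration", 30)
    outdir <- opt("out", "session_out")
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    imu <- make_imu_stream(function(t) 30 * sin(0.3 * t) * t / 10, dur,
                           imu_sim_config(gyro_noise_sd = 0.005,
                                          mag_noise_sd = 0.5,
                                          rng_seed = seed))
    sch <- acquisition_schedule(seq(5, dur - 2, by = 8), n_frames = 50L,
                                frame_interval_ms = 20, exposure_ms = 10)
    res <- run_session(mode, imu, sch, motor_config(backlash_usteps = 2L))
    write_imu_csv(imu, file.path(outdir, "imu.csv"))
    utils::write.csv(res$log, file.path(outdir, "joint_log.csv"),
                     row.names = FALSE)
    utils::write.csv(res$frames, file.path(outdir, "frames.csv"),
                     row.names = FALSE)
    logmsg(mode, " session simulated: ", nrow(res$frames), " frames, ",
           sum(res$log$event != ""), " events")
  } else if (cmd == "process-vsd") {
    st <- read_stack(opt("stack"))
    seqv <- list(frames = st$frames, dt_ms = st$dt_ms %||% 2,
                 preexposure_s = st$meta$preexposure_s %||% 1.5)
    dff <- compute_dff(seqv, ref_frame = as.integer(num("ref-frame", 10)))
    fit <- fit_bleach(dff, matrix(TRUE, dim(st$frames)[2],
                                  dim(st$frames)[3]))
    corr <- correct_bleach(dff, fit)
    outdir <- opt("out", "vsd_out")
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(list(poly = fit$poly, filter = fit$filter),
                         file.path(outdir, "bleach_fit.json"),
                         auto_unbox = TRUE, digits = NA)
    scaled <- pmin(pmax(round((corr$frames + 0.1) / 0.2 * 65535), 0), 65535)
    write_stack(scaled, file.path(outdir, "dff_corrected.tif"),
                dt_ms = seqv$dt_ms,
                extra = list(scaling = "dff = value/65535*0.2 - 0.1"))
    logmsg("corrected stack + fit written to ", outdir)
  } else if (cmd == "behavior-metrics") {
    traj <- read_trajectory_csv(opt("traj"))
    m <- session_metrics(traj)
    jsonlite::write_json(m, opt("out", "metrics.json"), auto_unbox = TRUE,
                         digits = NA)
    logmsg("metrics written")
  } else {
    stop("unknown command: ", cmd)
  }
  0L
}, error = function(e) {
  message("error: ", conditionMessage(e))
  1L
})
quit(status = status)
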