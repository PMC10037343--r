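# File formats tying the modules into pipelines: multi-page 16-bit TIFF
# stacks with a JSON metadata sidecar, IMU / trajectory / LUT CSV, report
# JSON.

sidecar_path <- function(path) paste0(path, ".json")

#' Write an image stack as multi-page 16-bit TIFF plus JSON sidecar
#'
#' Pixels are written losslessly as 16-bit TIFF pages; per-frame motor
#' angles and timing metadata go to a `<path>.json` sidecar.
#'
#' @param frames T x H x W array (or list of matrices) of integer counts in
#'   `[0, 65535]`.
#' @param path output TIFF path.
#' @param motor_angle_deg optional per-frame motor angles (length T).
#' @param dt_ms frame interval (ms).
#' @param t0_s acquisition start time (s).
#' @param extra named list of additional sidecar fields.
#' @return `path`, invisibly.
#' @export
write_stack <- function(frames, path, motor_angle_deg = NULL, dt_ms = NULL,
                        t0_s = 0, extra = list()) {
  if (is.list(frames) && !is.array(frames))
    frames <- simplify2array(frames)
  if (is.matrix(frames)) frames <- array(frames, c(1L, dim(frames)))
  if (length(dim(frames)) == 3L && !is.null(dimnames(frames))) dimnames(frames) <- NULL
  if (is.array(frames) && length(dim(frames)) == 3L &&
      dim(frames)[1] > dim(frames)[3])
    stop("frames must be a T x H x W array", call. = FALSE)
  T <- dim(frames)[1]
  if (!is.null(motor_angle_deg) && length(motor_angle_deg) != T)
    stop("motor angle list length must match the number of frames",
         call. = FALSE)
  if (any(frames < 0 | frames > 65535))
    stop("pixel values must fit 16 bits", call. = FALSE)
  pages <- lapply(seq_len(T), function(t)
    matrix(round(frames[t, , ]) / 65535, dim(frames)[2], dim(frames)[3]))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- c(list(n_frames = T, bit_depth = 16L,
                 motor_angle_deg = motor_angle_deg, dt_ms = dt_ms,
                 t0_s = t0_s), extra)
  meta <- meta[!vapply(meta, is.null, logical(1))]
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an image stack written by [write_stack()]
#'
#' @param path TIFF path; the `<path>.json` sidecar is read when present,
#'   otherwise metadata defaults are used with a warning.
#' @param as_integer return integer counts (TRUE) on the 16-bit scale.
#' @return list: `frames` (T x H x W array), `motor_angle_deg`, `dt_ms`,
#'   `t0_s`, plus any extra sidecar fields under `meta`.
#' @export
read_stack <- function(path, as_integer = TRUE) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  bits <- attr(pages[[1]], "bits.per.sample") %||% 16L
  if (bits != 16L)
    stop(sprintf("stack is %d-bit; explicit conversion to 16 bit required",
                 bits), call. = FALSE)
  frames <- array(0, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (t in seq_along(pages)) frames[t, , ] <- pages[[t]]
  sp <- sidecar_path(path)
  if (file.exists(sp)) {
    meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
    if (!is.null(meta$motor_angle_deg) &&
        length(meta$motor_angle_deg) != dim(frames)[1])
      stop("sidecar motor angle list length does not match frame count",
           call. = FALSE)
  } else {
    warning("no metadata sidecar found; using defaults")
    meta <- list()
  }
  list(frames = frames,
       motor_angle_deg = meta$motor_angle_deg %||% NULL,
       dt_ms = meta$dt_ms %||% NULL,
       t0_s = meta$t0_s %||% 0,
       meta = meta)
}

#' Write / read an IMU stream CSV
#'
#' Columns `t_s, gx, gy, gz, ax, ay, az, mx, my, mz` (gyro rad/s, accel g,
#' magnetometer uT).
#'
#' @param imu IMU data frame (see [make_imu_stream()]).
#' @param path CSV path.
#' @return `path` invisibly (write); the data frame (read).
#' @export
write_imu_csv <- function(imu, path) {
  utils::write.csv(imu, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_imu_csv
#' @export
read_imu_csv <- function(path) {
  imu <- utils::read.csv(path)
  need <- c("t_s", "gx", "gy", "gz", "ax", "ay", "az", "mx", "my", "mz")
  if (!all(need %in% names(imu)))
    stop("IMU CSV must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  imu
}

#' Write / read a tracked trajectory CSV
#'
#' Columns `t_s, x_mm, y_mm, conf, yaw_deg`.
#'
#' @param traj trajectory data frame (see [make_arena_trajectory()]).
#' @param path CSV path.
#' @return `path` invisibly (write); the data frame (read).
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(traj, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  traj <- utils::read.csv(path)
  need <- c("t_s", "x_mm", "y_mm", "conf", "yaw_deg")
  if (!all(need %in% names(traj)))
    stop("trajectory CSV must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  traj
}

#' Write / read a registration LUT CSV
#'
#' Columns `motor_angle_deg, theta_deg, tx_px, ty_px`; the rotation center
#' and OREF angle are stored in a `#`-comment header line.
#'
#' @param lut a [registration_lut()].
#' @param path CSV path.
#' @return `path` invisibly (write); the [registration_lut()] (read).
#' @export
write_lut_csv <- function(lut, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# center_x=%.6f center_y=%.6f oref_deg=%.6f",
                     lut$center_px[1], lut$center_px[2], lut$oref_deg), con)
  utils::write.csv(lut$entries, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lut_csv
#' @export
read_lut_csv <- function(path) {
  header <- readLines(path, n = 1L)
  vals <- as.numeric(sub(".*=", "", strsplit(sub("^# ", "", header),
                                             " ")[[1]]))
  entries <- utils::read.csv(path, comment.char = "#")
  registration_lut(entries, center_px = vals[1:2], oref_deg = vals[3])
}

#' Validated run configuration from JSON or YAML
#'
#' Reads a pipeline configuration file, rejecting unknown top-level keys.
#' Recognized blocks mirror the module configurations (`seed`, `scene`,
#' `capture`, `motor`, `vsd`, `imu`, `trajectory`, `mode`, `paths`).
#'
#' @param path `.json` or `.yaml`/`.yml` file.
#' @return the configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML configs", call. = FALSE)
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("seed", "scene", "capture", "motor", "vsd", "imu", "trajectory",
             "mode", "paths")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg
}
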