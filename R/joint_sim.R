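# Kinematic simulation of the motorized rotary joint: stepper geometry,
# dead-band backlash, anti-backlash locking at the reference orientation
# (OREF), and the three operating modes (HR lock, SR semi-continuous,
# hybrid unwind).

#' Motor and transmission configuration
#'
#' @param physical_steps_per_rev full steps per motor revolution (400).
#' @param microstepping driver microstepping factor (8).
#' @param gear_ratio output:input belt ratio (3); with the defaults one
#'   revolution of the main shaft subdivides into 9600 microsteps.
#' @param backlash_usteps mechanical backlash (lost motion on direction
#'   reversal), in microsteps of the output shaft.
#' @param max_speed_usteps_s rate limit for FOLLOW-mode motion.
#' @param approach_offset_deg anti-backlash overshoot: before each lock the
#'   motor first moves to OREF minus this offset, then approaches OREF in the
#'   fixed positive direction. Must exceed the backlash for the lock
#'   repeatability guarantee; defaults to twice the backlash (in degrees).
#' @param settle_s settle time after an SR per-frame stop (s).
#' @return a `motor_config` list.
#' @export
motor_config <- function(physical_steps_per_rev = 400L, microstepping = 8L,
                         gear_ratio = 3L, backlash_usteps = 0L,
                         max_speed_usteps_s = 48000,
                         approach_offset_deg = NULL, settle_s = 0) {
  check_scalar(physical_steps_per_rev, "physical_steps_per_rev", lower = 1,
               integer = TRUE)
  check_scalar(microstepping, "microstepping", lower = 1, integer = TRUE)
  check_scalar(gear_ratio, "gear_ratio", lower = 1, integer = TRUE)
  check_scalar(backlash_usteps, "backlash_usteps", lower = 0, integer = TRUE)
  check_scalar(max_speed_usteps_s, "max_speed_usteps_s", lower = 1e-9)
  check_scalar(settle_s, "settle_s", lower = 0)
  spr <- physical_steps_per_rev * microstepping * gear_ratio
  if (is.null(approach_offset_deg))
    approach_offset_deg <- 2 * backlash_usteps * 360 / spr
  check_scalar(approach_offset_deg, "approach_offset_deg", lower = 0)
  structure(list(physical_steps_per_rev = as.integer(physical_steps_per_rev),
                 microstepping = as.integer(microstepping),
                 gear_ratio = as.integer(gear_ratio),
                 backlash_usteps = as.integer(backlash_usteps),
                 max_speed_usteps_s = max_speed_usteps_s,
                 approach_offset_deg = approach_offset_deg,
                 settle_s = settle_s),
            class = "motor_config")
}

#' Microsteps per output-shaft revolution
#'
#' `physical_steps_per_rev * microstepping * gear_ratio`: 9600 for the
#' default 400-step motor at x8 microstepping behind a 1:3 belt.
#'
#' @param cfg a [motor_config()].
#' @return integer microstep count.
#' @export
steps_per_revolution <- function(cfg = motor_config()) {
  cfg$physical_steps_per_rev * cfg$microstepping * cfg$gear_ratio
}

#' Joint state
#'
#' Commanded and realized output positions in output-shaft microsteps, the
#' backlash engagement direction, the operating-mode flag, and the OREF
#' position. `abs(commanded - output) <= backlash` at all times.
#'
#' @param commanded_usteps commanded position.
#' @param output_usteps realized output position.
#' @param engaged_dir +1, -1 (dead-band contact side) or 0 (never engaged).
#' @param mode one of FOLLOW, HR_LOCKED, SR, HYBRID.
#' @param oref_usteps OREF position in microsteps.
#' @return a `joint_state` list.
#' @export
joint_state <- function(commanded_usteps = 0L, output_usteps = 0L,
                        engaged_dir = 0L,
                        mode = c("FOLLOW", "HR_LOCKED", "SR", "HYBRID"),
                        oref_usteps = 0L) {
  mode <- match.arg(mode)
  structure(list(commanded_usteps = as.numeric(commanded_usteps),
                 output_usteps = as.numeric(output_usteps),
                 engaged_dir = as.integer(engaged_dir), mode = mode,
                 oref_usteps = as.numeric(oref_usteps)),
            class = "joint_state")
}

#' Move the motor through the backlash dead band
#'
#' Advances the commanded position by `delta_usteps`. While engaged, output
#' tracks commanded 1:1; on a direction reversal the first `backlash_usteps`
#' of commanded motion are absorbed by the dead band and produce no output
#' motion.
#'
#' @param state a [joint_state()].
#' @param delta_usteps signed commanded increment.
#' @param cfg a [motor_config()].
#' @return the updated state.
#' @export
command_move <- function(state, delta_usteps, cfg = motor_config()) {
  u <- state$commanded_usteps + delta_usteps
  y <- state$output_usteps
  B <- cfg$backlash_usteps
  dir <- state$engaged_dir
  if (u > y) {
    y <- u; dir <- 1L
  } else if (u < y - B) {
    y <- u + B; dir <- -1L
  }
  state$commanded_usteps <- u
  state$output_usteps <- y
  state$engaged_dir <- dir
  state
}

#' Lock the joint at OREF with the anti-backlash approach
#'
#' The motor first reaches a position shifted from OREF by the approach
#' offset (greater than the backlash), then moves to OREF always in the same
#' (positive) direction. The realized lock angle is therefore identical
#' across locks regardless of the prior motion history.
#'
#' @param state a [joint_state()].
#' @param cfg a [motor_config()]; `approach_offset_deg` (in microsteps) must
#'   exceed `backlash_usteps` whenever the backlash is non-zero.
#' @return the locked state (`mode = "HR_LOCKED"`, output exactly at OREF).
#' @export
lock_at_oref <- function(state, cfg = motor_config()) {
  spr <- steps_per_revolution(cfg)
  approach <- round(cfg$approach_offset_deg * spr / 360)
  if (cfg$backlash_usteps > 0 && approach <= cfg$backlash_usteps)
    stop_config("approach_offset_deg",
                "must exceed the backlash for a repeatable lock")
  pre <- state$oref_usteps - approach
  state <- command_move(state, pre - state$commanded_usteps, cfg)
  state <- command_move(state, approach, cfg)
  state$mode <- "HR_LOCKED"
  state
}

#' Release a lock back to FOLLOW mode
#' @param state a [joint_state()].
#' @return the state with `mode = "FOLLOW"`.
#' @export
unlock <- function(state) {
  state$mode <- "FOLLOW"
  state
}

#' Track the (unwrapped) head yaw
#'
#' Moves the commanded position toward `target_yaw * steps_per_rev / 360`,
#' rate-limited by the motor's maximum speed. The target is the *unwrapped*
#' yaw: fiber torsion is what is being tracked, so a 720-degree target means
#' two full output turns, never the shortest path modulo 360.
#'
#' @param state a [joint_state()] (not HR-locked).
#' @param target_yaw_unwrapped_deg target orientation, unwrapped degrees.
#' @param cfg a [motor_config()].
#' @param dt_s elapsed time for the rate limit (s, > 0).
#' @return the updated state.
#' @export
follow <- function(state, target_yaw_unwrapped_deg, cfg = motor_config(),
                   dt_s = 0.02) {
  if (state$mode == "HR_LOCKED")
    stop("cannot follow while HR-locked; unlock first", call. = FALSE)
  if (dt_s <= 0) stop("dt_s must be > 0", call. = FALSE)
  spr <- steps_per_revolution(cfg)
  target <- round(target_yaw_unwrapped_deg * spr / 360)
  delta <- target - state$commanded_usteps
  max_move <- floor(cfg$max_speed_usteps_s * dt_s)
  delta <- max(-max_move, min(max_move, delta))
  command_move(state, delta, cfg)
}

output_deg <- function(state, cfg) {
  state$output_usteps * 360 / steps_per_revolution(cfg)
}

#' Acquisition schedule
#'
#' @param trigger_s sequence trigger times (s), strictly increasing.
#' @param n_frames frames per sequence.
#' @param frame_interval_ms frame-to-frame interval (ms).
#' @param exposure_ms exposure time per frame (ms), at most the interval.
#' @return an `acquisition_schedule` list.
#' @export
acquisition_schedule <- function(trigger_s, n_frames = 512L,
                                 frame_interval_ms = 2, exposure_ms = 2) {
  if (length(trigger_s) < 1L || any(!is.finite(trigger_s)))
    stop_config("trigger_s", "must be finite times")
  check_scalar(n_frames, "n_frames", lower = 1, integer = TRUE)
  check_scalar(frame_interval_ms, "frame_interval_ms", lower = 1e-9)
  check_scalar(exposure_ms, "exposure_ms", lower = 1e-9,
               upper = frame_interval_ms)
  dur <- n_frames * frame_interval_ms / 1000
  if (length(trigger_s) > 1L) {
    if (any(diff(trigger_s) <= 0))
      stop_config("trigger_s", "must be strictly increasing")
    if (any(diff(trigger_s) < dur))
      stop_config("trigger_s", "sequences overlap")
  }
  structure(list(trigger_s = as.numeric(trigger_s),
                 n_frames = as.integer(n_frames),
                 frame_interval_ms = frame_interval_ms,
                 exposure_ms = exposure_ms, duration_s = dur),
            class = "acquisition_schedule")
}

#' Simulate a full acquisition session in one operating mode
#'
#' Runs the orientation filter over the IMU stream, drives the joint at the
#' IMU tick rate, and logs motor state, lock/unlock/unwind events, per-frame
#' motor angles and the fiber-torsion trace (unwrapped yaw minus output
#' angle).
#'
#' Modes: `HR` locks at OREF (anti-backlash approach) for every acquisition
#' sequence and follows the animal in between; `SR` keeps following
#' semi-continuously but holds the motor still during each frame's exposure
#' window; `HYBRID` stays locked at OREF and performs a fast one-revolution
#' unwind whenever the accumulated torsion reaches 360 degrees.
#'
#' @param mode `"HR"`, `"SR"` or `"HYBRID"`.
#' @param imu IMU stream data frame (see [make_imu_stream()]).
#' @param schedule an [acquisition_schedule()].
#' @param cfg a [motor_config()]. For SR the frame interval must leave room
#'   for exposure plus settle time.
#' @param p [filter_params()] for the orientation filter.
#' @param oref_deg OREF orientation in degrees.
#' @return a list: `log` (per-tick data frame `t_s, commanded_usteps,
#'   output_deg, mode, event`), `frames` (per-frame data frame `seq, frame,
#'   t_s, motor_deg`), `torsion_deg` (per-tick), `yaw_deg` (per-tick
#'   unwrapped filter yaw).
#' @export
run_session <- function(mode = c("HR", "SR", "HYBRID"), imu, schedule,
                        cfg = motor_config(), p = filter_params(),
                        oref_deg = 0) {
  mode <- match.arg(mode)
  stopifnot(inherits(schedule, "acquisition_schedule"))
  if (mode == "SR" &&
      schedule$frame_interval_ms / 1000 <=
        schedule$exposure_ms / 1000 + cfg$settle_s)
    stop("scheduling error: SR frame interval leaves no time to move",
         call. = FALSE)

  orient <- madgwick_filter(imu, p)
  yaw <- unwrap_yaw(orient$yaw_deg)
  t <- orient$t_s
  n <- length(t)
  spr <- steps_per_revolution(cfg)
  oref_usteps <- round(oref_deg * spr / 360)
  st <- joint_state(commanded_usteps = oref_usteps,
                    output_usteps = oref_usteps,
                    oref_usteps = oref_usteps)

  # frame times for every sequence
  frame_t <- lapply(seq_along(schedule$trigger_s), function(si) {
    schedule$trigger_s[si] +
      (seq_len(schedule$n_frames) - 1L) * schedule$frame_interval_ms / 1000
  })
  seq_start <- schedule$trigger_s
  seq_end <- schedule$trigger_s + schedule$duration_s

  log_cmd <- numeric(n); log_out <- numeric(n)
  log_mode <- character(n); log_event <- character(n)
  torsion <- numeric(n)
  locked_seq <- 0L      # index of the sequence currently locked for (HR)
  unwind_turns <- 0L

  if (mode == "HYBRID") st <- lock_at_oref(st, cfg)

  for (i in seq_len(n)) {
    ev <- ""
    dt <- if (i > 1L) t[i] - t[i - 1] else if (n > 1L) t[2] - t[1] else 0.02

    if (mode == "HR") {
      active <- which(t[i] >= seq_start & t[i] <= seq_end)
      if (length(active) && locked_seq != active[1]) {
        # lock at the nearest 360-degree equivalent of OREF to minimize the
        # torsion jump (all equivalents present the same field to the sensor)
        st$oref_usteps <- oref_usteps +
          spr * round((st$commanded_usteps - oref_usteps) / spr)
        st <- lock_at_oref(st, cfg)
        locked_seq <- active[1]
        ev <- "lock"
      } else if (!length(active)) {
        if (st$mode == "HR_LOCKED") { st <- unlock(st); ev <- "unlock" }
        st <- follow(st, yaw[i], cfg, dt)
      }
    } else if (mode == "SR") {
      in_exposure <- any(vapply(frame_t, function(ft) {
        any(t[i] >= ft & t[i] <= ft + schedule$exposure_ms / 1000)
      }, logical(1)))
      if (!in_exposure) st <- follow(st, yaw[i], cfg, dt)
      st$mode <- "SR"
    } else { # HYBRID
      tor <- yaw[i] - st$output_usteps * 360 / spr
      if (abs(tor) >= 360) {
        jump <- sign(tor) * spr
        st <- command_move(st, jump, cfg)
        unwind_turns <- unwind_turns + 1L
        ev <- "unwind"
      }
      st$mode <- "HYBRID"
    }

    log_cmd[i] <- st$commanded_usteps
    log_out[i] <- output_deg(st, cfg)
    log_mode[i] <- st$mode
    log_event[i] <- ev
    torsion[i] <- yaw[i] - log_out[i]
  }

  # per-frame motor angle: output at the last tick at or before each frame
  frames <- do.call(rbind, lapply(seq_along(frame_t), function(si) {
    ft <- frame_t[[si]]
    idx <- findInterval(ft, t)
    idx[idx < 1L] <- 1L
    data.frame(seq = si, frame = seq_along(ft), t_s = ft,
               motor_deg = log_out[idx])
  }))

  list(log = data.frame(t_s = t, commanded_usteps = log_cmd,
                        output_deg = log_out, mode = log_mode,
                        event = log_event),
       frames = frames, torsion_deg = torsion, yaw_deg = yaw)
}
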