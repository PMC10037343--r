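# Absolute head-yaw estimation from 9-DoF IMU samples: Madgwick
# gradient-descent quaternion fusion, hard-iron magnetometer calibration,
# yaw extraction and unwrapping.
#
# Conventions: quaternions are (w, x, y, z), unit norm, and rotate body-frame
# vectors into the world frame (v_world = q (x) v_body (x) q*). The world
# frame has z up (gravity reads +1 g on a level accelerometer) and x along
# magnetic north; yaw is the rotation about world z, counter-clockwise
# positive, extracted in ZYX order.

quat_normalize <- function(q) {
  n <- sqrt(sum(q^2))
  if (n < 1e-12) stop("zero-norm quaternion", call. = FALSE)
  q / n
}

quat_multiply <- function(p, q) {
  c(p[1] * q[1] - p[2] * q[2] - p[3] * q[3] - p[4] * q[4],
    p[1] * q[2] + p[2] * q[1] + p[3] * q[4] - p[4] * q[3],
    p[1] * q[3] - p[2] * q[4] + p[3] * q[1] + p[4] * q[2],
    p[1] * q[4] + p[2] * q[3] - p[3] * q[2] + p[4] * q[1])
}

quat_conj <- function(q) c(q[1], -q[2], -q[3], -q[4])

# rotate a body-frame vector into the world frame
quat_rotate <- function(q, v) {
  quat_multiply(quat_multiply(q, c(0, v)), quat_conj(q))[2:4]
}

# rotate a world-frame vector into the body frame
quat_rotate_inv <- function(q, v) {
  quat_multiply(quat_multiply(quat_conj(q), c(0, v)), q)[2:4]
}

# quaternion from a body->world rotation matrix (Shepperd's method)
quat_from_matrix <- function(C) {
  tr <- C[1, 1] + C[2, 2] + C[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (C[3, 2] - C[2, 3]) / s, (C[1, 3] - C[3, 1]) / s,
           (C[2, 1] - C[1, 2]) / s)
  } else {
    i <- which.max(c(C[1, 1], C[2, 2], C[3, 3]))
    if (i == 1) {
      s <- sqrt(1 + C[1, 1] - C[2, 2] - C[3, 3]) * 2
      q <- c((C[3, 2] - C[2, 3]) / s, s / 4, (C[1, 2] + C[2, 1]) / s,
             (C[1, 3] + C[3, 1]) / s)
    } else if (i == 2) {
      s <- sqrt(1 - C[1, 1] + C[2, 2] - C[3, 3]) * 2
      q <- c((C[1, 3] - C[3, 1]) / s, (C[1, 2] + C[2, 1]) / s, s / 4,
             (C[2, 3] + C[3, 2]) / s)
    } else {
      s <- sqrt(1 - C[1, 1] - C[2, 2] + C[3, 3]) * 2
      q <- c((C[2, 1] - C[1, 2]) / s, (C[1, 3] + C[3, 1]) / s,
             (C[2, 3] + C[3, 2]) / s, s / 4)
    }
  }
  quat_normalize(q)
}

#' Madgwick filter parameters
#'
#' @param beta gradient-descent gain (dimensionless, > 0). The default 0.1 is
#'   the published recommendation for MARG (gyro + accel + mag) operation.
#' @param init_mode `"accel_mag"` initializes from the first
#'   accelerometer/magnetometer pair (TRIAD-style, giving absolute yaw from
#'   the first sample); `"identity"` starts at the identity quaternion.
#' @return a `filter_params` list.
#' @export
filter_params <- function(beta = 0.1, init_mode = c("accel_mag", "identity")) {
  check_scalar(beta, "beta", lower = 1e-12)
  init_mode <- match.arg(init_mode)
  structure(list(beta = beta, init_mode = init_mode),
            class = "filter_params")
}

#' Orientation estimate
#'
#' @param q unit quaternion `(w, x, y, z)` rotating body vectors into the
#'   world frame.
#' @param t_s timestamp, seconds.
#' @return an `orientation_estimate` with fields `q`, `yaw_deg`, `t_s`.
#' @export
orientation_estimate <- function(q = c(1, 0, 0, 0), t_s = 0) {
  q <- quat_normalize(as.numeric(q))
  structure(list(q = q, yaw_deg = yaw_of(q), t_s = t_s),
            class = "orientation_estimate")
}

#' Hard-iron magnetometer calibration
#'
#' Fits, by linear least squares, the center of the sphere that best explains
#' a cloud of magnetometer readings taken while the sensor sweeps multiple
#' headings; the center is the hard-iron offset to subtract from subsequent
#' readings.
#'
#' @param mag_samples numeric matrix (n x 3) or data frame of field readings.
#' @return the offset 3-vector.
#' @export
calibrate_hard_iron <- function(mag_samples) {
  m <- as.matrix(mag_samples)
  if (ncol(m) != 3L) stop("mag_samples must have 3 columns", call. = FALSE)
  if (nrow(m) < 4L)
    stop("calibration error: need at least 4 magnetometer samples",
         call. = FALSE)
  centered <- sweep(m, 2, colMeans(m))
  sv <- svd(centered)$d
  if (sv[3] < 1e-8 * max(sv[1], 1e-300))
    stop("calibration error: degenerate sample cloud (rank < 3)",
         call. = FALSE)
  A <- cbind(2 * m, 1)
  y <- rowSums(m^2)
  beta <- qr.solve(A, y)
  beta[1:3]
}

# Measurement prediction for the fused objective: body-frame gravity and
# flux given orientation q and earth flux direction b = (bx, 0, bz).
marg_objective <- function(q, a, m, b) {
  c(quat_rotate_inv(q, c(0, 0, 1)) - a,
    quat_rotate_inv(q, b) - m)
}

#' Single Madgwick MARG filter update
#'
#' One step of the gradient-descent orientation filter: the quaternion is
#' propagated by gyro integration and corrected by a normalized gradient step
#' on the joint accelerometer (gravity) + magnetometer (flux) objective. The
#' earth-frame flux reference is re-derived from the current estimate at each
#' step, so only the yaw component is anchored by the magnetometer and the
#' magnetic inclination does not tilt the estimate. With `beta = 0` the update
#' is pure gyro integration; if the accelerometer or magnetometer reading has
#' zero norm the correction step is skipped.
#'
#' @param state an [orientation_estimate()].
#' @param sample one IMU sample: list/row with `gx, gy, gz` (rad/s),
#'   `ax, ay, az` (g), `mx, my, mz` (uT).
#' @param dt_s time step, seconds (> 0).
#' @param p a [filter_params()].
#' @return the updated [orientation_estimate()].
#' @export
madgwick_update <- function(state, sample, dt_s, p = filter_params()) {
  if (!is.numeric(dt_s) || length(dt_s) != 1L || !is.finite(dt_s) ||
      dt_s <= 0)
    stop("dt_s must be > 0", call. = FALSE)
  q <- state$q
  g <- c(sample$gx, sample$gy, sample$gz)
  a <- c(sample$ax, sample$ay, sample$az)
  m <- c(sample$mx, sample$my, sample$mz)
  # exact exponential-map gyro propagation (stays accurate at fast rates,
  # where the first-order q + q_dot*dt update under-rotates), followed by
  # the gradient correction evaluated at the propagated state — the
  # measurement is concurrent with the end of the step
  ang <- sqrt(sum(g^2)) * dt_s
  dq <- if (ang > 1e-12) c(cos(ang / 2), g / sqrt(sum(g^2)) * sin(ang / 2))
  else c(1, 0, 0, 0)
  q <- quat_multiply(q, dq)

  na <- sqrt(sum(a^2)); nm <- sqrt(sum(m^2))
  if (p$beta > 0 && na > 1e-12 && nm > 1e-12) {
    a <- a / na; m <- m / nm
    h <- quat_rotate(q, m)                     # measured flux in world frame
    b <- c(sqrt(h[1]^2 + h[2]^2), 0, h[3])     # reference direction
    f0 <- marg_objective(q, a, m, b)
    J <- matrix(0, 6L, 4L)                     # numerical Jacobian d f / d q
    eps <- 1e-6
    for (k in 1:4) {
      qp <- q; qp[k] <- qp[k] + eps
      qm <- q; qm[k] <- qm[k] - eps
      J[, k] <- (marg_objective(qp, a, m, b) -
                   marg_objective(qm, a, m, b)) / (2 * eps)
    }
    grad <- drop(crossprod(J, f0))
    ng <- sqrt(sum(grad^2))
    # residual-proportional gain boost: accelerates initial convergence from
    # a poor attitude (large objective norm) while leaving the steady-state
    # gain at beta once the estimate is close
    beta_eff <- p$beta * (1 + 9 * min(1, sqrt(sum(f0^2))))
    if (ng > 1e-12) q <- q - beta_eff * dt_s * grad / ng
  }
  q <- quat_normalize(q)
  structure(list(q = q, yaw_deg = yaw_of(q), t_s = state$t_s + dt_s),
            class = "orientation_estimate")
}

# TRIAD-style initial attitude from one accel + mag pair.
triad_init <- function(a, m) {
  up <- a / sqrt(sum(a^2))
  mh <- m - sum(m * up) * up                 # horizontal flux = north in body
  if (sqrt(sum(mh^2)) < 1e-9) return(c(1, 0, 0, 0))
  north <- mh / sqrt(sum(mh^2))
  east <- c(up[2] * north[3] - up[3] * north[2],
            up[3] * north[1] - up[1] * north[3],
            up[1] * north[2] - up[2] * north[1])  # y = z x x
  C <- rbind(north, east, up)                # body->world rotation matrix
  quat_from_matrix(C)
}

#' Run the Madgwick filter over an IMU stream
#'
#' @param imu data frame with columns `t_s, gx, gy, gz, ax, ay, az, mx, my,
#'   mz` (monotone timestamps).
#' @param p a [filter_params()].
#' @param mag_offset optional hard-iron offset (from
#'   [calibrate_hard_iron()]) subtracted from the magnetometer columns.
#' @return a data frame `t_s, qw, qx, qy, qz, yaw_deg`.
#' @export
madgwick_filter <- function(imu, p = filter_params(), mag_offset = c(0, 0, 0)) {
  need <- c("t_s", "gx", "gy", "gz", "ax", "ay", "az", "mx", "my", "mz")
  if (!all(need %in% names(imu)))
    stop("imu stream must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  n <- nrow(imu)
  if (n < 1L) stop("empty IMU stream", call. = FALSE)
  if (any(diff(imu$t_s) <= 0))
    stop("IMU timestamps must be strictly increasing", call. = FALSE)
  imu$mx <- imu$mx - mag_offset[1]
  imu$my <- imu$my - mag_offset[2]
  imu$mz <- imu$mz - mag_offset[3]

  q0 <- if (p$init_mode == "accel_mag")
    triad_init(c(imu$ax[1], imu$ay[1], imu$az[1]),
               c(imu$mx[1], imu$my[1], imu$mz[1]))
  else c(1, 0, 0, 0)
  state <- structure(list(q = q0, yaw_deg = yaw_of(q0), t_s = imu$t_s[1]),
                     class = "orientation_estimate")

  out <- matrix(0, n, 5L)
  out[1, ] <- c(state$q, state$yaw_deg)
  if (n > 1L) {
    for (i in 2:n) {
      # midpoint-rule gyro over the step: halves the integration lag of the
      # rectangle rule at high yaw rates
      s <- imu[i, ]
      s$gx <- (s$gx + imu$gx[i - 1]) / 2
      s$gy <- (s$gy + imu$gy[i - 1]) / 2
      s$gz <- (s$gz + imu$gz[i - 1]) / 2
      state <- madgwick_update(state, s, imu$t_s[i] - imu$t_s[i - 1], p)
      out[i, ] <- c(state$q, state$yaw_deg)
    }
  }
  data.frame(t_s = imu$t_s, qw = out[, 1], qx = out[, 2], qy = out[, 3],
             qz = out[, 4], yaw_deg = out[, 5])
}

#' Yaw (heading) of a quaternion
#'
#' ZYX Euler extraction of the rotation about the world z-axis, in degrees on
#' the principal branch (-180, 180].
#'
#' @param q quaternion `(w, x, y, z)`, approximately unit norm.
#' @return yaw in degrees.
#' @export
yaw_of <- function(q) {
  if (sqrt(sum(q^2)) < 1e-12) stop("zero quaternion", call. = FALSE)
  wrap180(rad2deg(atan2(2 * (q[1] * q[4] + q[2] * q[3]),
                        1 - 2 * (q[3]^2 + q[4]^2))))
}

#' Unwrap a yaw series into a continuous angle
#'
#' Removes the 360-degree jumps of a principal-branch yaw series, assuming the
#' true rotation between successive samples is below 180 degrees. The result
#' differs from the input by an integer multiple of 360 at every sample.
#'
#' @param yaw_series yaw values in degrees.
#' @return the unwrapped series.
#' @export
unwrap_yaw <- function(yaw_series) {
  if (length(yaw_series) == 0L)
    stop("empty yaw series", call. = FALSE)
  d <- wrap180(diff(yaw_series))
  cumsum(c(yaw_series[1], d))
}
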