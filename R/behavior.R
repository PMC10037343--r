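# Mobility metrics for freely-moving sessions: cumulated revolutions and
# their time-weighted distribution (D9/Q2), mean angular velocity, mean
# displacement, and paired condition comparisons.

#' Drop low-confidence tracking frames
#'
#' Frames where any tracked-point confidence falls below the threshold are
#' removed; gaps are left as-is (not interpolated) and are later excluded
#' from pairwise velocity metrics.
#'
#' @param traj trajectory data frame with a `conf` column (or several
#'   columns whose names start with `conf`).
#' @param threshold confidence threshold in `[0, 1]`.
#' @return the filtered trajectory.
#' @export
filter_low_confidence <- function(traj, threshold) {
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1)
    stop("threshold must be in [0, 1]", call. = FALSE)
  cols <- grep("^conf", names(traj), value = TRUE)
  if (length(cols) == 0L) stop("no confidence column found", call. = FALSE)
  keep <- Reduce(`&`, lapply(cols, function(cn) traj[[cn]] >= threshold))
  traj[keep, , drop = FALSE]
}

#' Cumulated revolutions relative to the session start
#'
#' @param yaw_deg unwrapped yaw series, degrees.
#' @return signed revolutions `(yaw - yaw[1]) / 360`.
#' @export
cumulative_revolutions <- function(yaw_deg) {
  if (length(yaw_deg) == 0L) stop("empty yaw series", call. = FALSE)
  (yaw_deg - yaw_deg[1]) / 360
}

# Time spent with |r(t)| <= u, treating r as piecewise linear between
# samples. Segments crossing zero are split there so |r| is linear on each
# piece; everything is vectorized over segments.
make_abs_segments <- function(rev, t_s) {
  n <- length(rev)
  a <- rev[-n]; b <- rev[-1]; d <- diff(t_s)
  cross <- a * b < 0
  s <- ifelse(cross, a / (a - b), 1)
  lo1 <- abs(a); hi1 <- ifelse(cross, 0, abs(b)); d1 <- d * s
  lo2 <- rep(0, n - 1L); hi2 <- abs(b); d2 <- d * (1 - s)
  keep2 <- cross
  list(lo = pmin(c(lo1, lo2[keep2]), c(hi1, hi2[keep2])),
       hi = pmax(c(lo1, lo2[keep2]), c(hi1, hi2[keep2])),
       d = c(d1, d2[keep2]))
}

time_below_segments <- function(u, seg) {
  full <- seg$hi <= u
  partial <- !full & seg$lo < u
  sum(seg$d[full]) +
    sum(seg$d[partial] * (u - seg$lo[partial]) /
          (seg$hi[partial] - seg$lo[partial]))
}

time_below <- function(u, rev, t_s) {
  time_below_segments(u, make_abs_segments(rev, t_s))
}

#' Time-weighted distribution of cumulated revolutions
#'
#' Treats the revolution series as piecewise linear in time and computes the
#' exact time-weighted distribution of its magnitude: a histogram of the
#' fraction of session time spent at each amount of cumulated rotation, plus
#' the D9 (90% of time spent below) and Q2 (median) quantiles.
#'
#' @param revolutions signed revolutions series (from
#'   [cumulative_revolutions()]).
#' @param t_s sample times, strictly increasing, seconds.
#' @param bin_width histogram bin width in revolutions.
#' @return list: `histogram` (data frame `lower, upper, fraction` summing to
#'   1), `d9`, `q2`, `total_time_s`, and `quantile(q)` — the time-weighted
#'   quantile function of `|revolutions|` for `q` in (0, 1).
#' @export
revolution_time_stats <- function(revolutions, t_s, bin_width = 0.25) {
  n <- length(revolutions)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  if (length(t_s) != n || any(diff(t_s) <= 0))
    stop("time must be strictly increasing and match the series",
         call. = FALSE)
  check_scalar(bin_width, "bin_width", lower = 1e-12)
  total <- t_s[n] - t_s[1]
  rmax <- max(abs(revolutions))
  seg <- make_abs_segments(revolutions, t_s)
  qfun <- function(q) {
    if (!is.numeric(q) || q <= 0 || q >= 1)
      stop("quantile level must be in (0, 1)", call. = FALSE)
    if (rmax == 0) return(0)
    target <- q * total
    if (time_below_segments(0, seg) >= target) return(0)
    stats::uniroot(function(u) time_below_segments(u, seg) - target,
                   c(0, rmax), tol = 1e-10)$root
  }
  edges <- seq(0, (floor(rmax / bin_width) + 1L) * bin_width, by = bin_width)
  below <- vapply(edges, time_below_segments, numeric(1), seg = seg)
  hist <- data.frame(lower = edges[-length(edges)], upper = edges[-1],
                     fraction = diff(below) / total)
  # mass sitting exactly at 0 belongs to the first bin
  hist$fraction[1] <- hist$fraction[1] + below[1] / total
  list(histogram = hist, d9 = qfun(0.9), q2 = qfun(0.5),
       total_time_s = total, quantile = qfun)
}

#' Mean angular velocity of head rotations
#'
#' Mean of `|d yaw / dt|` over retained consecutive sample pairs; pairs
#' spanning removed (low-confidence) gaps are excluded via the gap
#' threshold.
#'
#' @param yaw_deg unwrapped yaw, degrees.
#' @param t_s sample times, seconds.
#' @param max_gap_s pairs further apart than this are skipped; defaults to
#'   3x the median sampling interval.
#' @return mean angular speed, deg/s.
#' @export
mean_angular_velocity <- function(yaw_deg, t_s, max_gap_s = NULL) {
  if (length(yaw_deg) < 2L) stop("need at least 2 samples", call. = FALSE)
  dt <- diff(t_s)
  if (any(dt <= 0)) stop("time must be strictly increasing", call. = FALSE)
  if (is.null(max_gap_s)) max_gap_s <- 3 * stats::median(dt)
  keep <- dt <= max_gap_s
  if (!any(keep)) stop("no retained sample pairs", call. = FALSE)
  mean(abs(diff(yaw_deg)[keep] / dt[keep]))
}

#' Mean displacement speed
#'
#' Mean of `||d position|| / dt` over retained consecutive frame pairs,
#' excluding pairs spanning removed gaps.
#'
#' @param traj trajectory data frame with `t_s, x_mm, y_mm`.
#' @param max_gap_s gap-exclusion threshold; defaults to 3x the median
#'   sampling interval.
#' @return mean displacement speed, mm/s.
#' @export
mean_displacement <- function(traj, max_gap_s = NULL) {
  if (nrow(traj) < 2L) stop("need at least 2 retained frames", call. = FALSE)
  dt <- diff(traj$t_s)
  if (any(dt <= 0)) stop("time must be strictly increasing", call. = FALSE)
  if (is.null(max_gap_s)) max_gap_s <- 3 * stats::median(dt)
  keep <- dt <= max_gap_s
  if (!any(keep)) stop("no retained frame pairs", call. = FALSE)
  step <- sqrt(diff(traj$x_mm)^2 + diff(traj$y_mm)^2)
  mean(step[keep] / dt[keep])
}

#' Summary metrics for one behavioral session
#'
#' @param traj trajectory data frame `t_s, x_mm, y_mm, conf, yaw_deg` (yaw
#'   unwrapped).
#' @param conf_threshold confidence cutoff applied first.
#' @param bin_width revolution histogram bin width.
#' @return list: `d9_revolutions, q2_revolutions, mean_ang_vel_deg_s,
#'   mean_disp_mm_per_s, revolution_histogram`.
#' @export
session_metrics <- function(traj, conf_threshold = 0.6, bin_width = 0.25) {
  traj <- filter_low_confidence(traj, conf_threshold)
  if (nrow(traj) < 2L) stop("too few retained frames", call. = FALSE)
  rev <- cumulative_revolutions(traj$yaw_deg)
  st <- revolution_time_stats(rev, traj$t_s, bin_width)
  list(d9_revolutions = st$d9, q2_revolutions = st$q2,
       mean_ang_vel_deg_s = mean_angular_velocity(traj$yaw_deg, traj$t_s),
       mean_disp_mm_per_s = mean_displacement(traj),
       revolution_histogram = st$histogram)
}

#' Paired comparison of per-animal session values
#'
#' Two-sided paired tests of the active-joint vs inactive-joint condition
#' values: Wilcoxon signed-rank on the distributions or paired t-test.
#'
#' @param active,inactive paired per-animal values.
#' @param test `"wilcoxon"` or `"paired_t"`.
#' @return list `statistic`, `p_value`, `test`.
#' @export
compare_conditions <- function(active, inactive,
                               test = c("wilcoxon", "paired_t")) {
  test <- match.arg(test)
  if (length(active) != length(inactive))
    stop("paired values must have equal length", call. = FALSE)
  d <- active - inactive
  if (test == "wilcoxon") {
    if (all(d == 0))
      return(list(statistic = NA_real_, p_value = 1, test = test))
    res <- suppressWarnings(stats::wilcox.test(active, inactive,
                                               paired = TRUE))
  } else {
    if (length(d) < 2L)
      stop("paired t-test needs at least 2 pairs", call. = FALSE)
    if (stats::sd(d) == 0)
      return(list(statistic = if (all(d == 0)) NA_real_ else Inf * sign(d[1]),
                  p_value = if (all(d == 0)) 1 else 0, test = test))
    res <- stats::t.test(active, inactive, paired = TRUE)
  }
  list(statistic = unname(res$statistic), p_value = res$p.value, test = test)
}
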