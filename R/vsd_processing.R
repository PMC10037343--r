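# Voltage-sensitive-dye signal chain: dF/F0 normalization, photobleaching
# fit and correction, bleach-vs-pre-exposure regression, Fourier-domain
# patterned-noise removal, spatial smoothing.
#
# Sequences are lists with `frames` (T x H x W array), `dt_ms`,
# `preexposure_s`, `units` ("counts" or "dff") and optionally `valid`
# (H x W logical); plain T x H x W arrays are accepted where noted and
# returned as arrays.

as_fluo_seq <- function(seq, dt_ms = NULL, preexposure_s = NULL,
                        units = "counts") {
  if (is.array(seq) && length(dim(seq)) == 3L)
    return(list(frames = seq, dt_ms = dt_ms %||% 1,
                preexposure_s = preexposure_s %||% 0, units = units))
  if (is.list(seq) && !is.null(seq$frames))
    return(list(frames = seq$frames, dt_ms = seq$dt_ms %||% dt_ms %||% 1,
                preexposure_s = seq$preexposure_s %||% preexposure_s %||% 0,
                units = seq$units %||% units, valid = seq$valid))
  stop("expected a T x H x W array or a sequence list with $frames",
       call. = FALSE)
}

seq_times_s <- function(s) {
  s$preexposure_s + (seq_len(dim(s$frames)[1]) - 1L) * s$dt_ms / 1000
}

#' Pixel-wise dF/F0 normalization
#'
#' `F0` is the per-pixel mean of the three frames centered on `ref_frame`;
#' the output is `(F - F0) / F0`. Pixels with `F0 <= 0` are flagged invalid
#' (NA in the output, FALSE in the `valid` mask) rather than producing
#' infinities.
#'
#' @param seq fluorescence sequence (list with `frames` or T x H x W array),
#'   in counts.
#' @param ref_frame reference frame index (1-based); the window
#'   `ref_frame - 1 .. ref_frame + 1` must be inside the sequence.
#' @return a sequence list in dF/F units with a `valid` mask.
#' @export
compute_dff <- function(seq, ref_frame) {
  s <- as_fluo_seq(seq)
  T <- dim(s$frames)[1]
  if (!is.numeric(ref_frame) || ref_frame != round(ref_frame) ||
      ref_frame < 2 || ref_frame > T - 1)
    stop("ref_frame window out of range (need 2 <= ref_frame <= T-1)",
         call. = FALSE)
  f0 <- (s$frames[ref_frame - 1, , ] + s$frames[ref_frame, , ] +
           s$frames[ref_frame + 1, , ]) / 3
  valid <- f0 > 0
  dff <- array(NA_real_, dim(s$frames))
  f0_safe <- ifelse(valid, f0, 1)
  for (t in seq_len(T)) {
    d <- (s$frames[t, , ] - f0) / f0_safe
    d[!valid] <- NA_real_
    dff[t, , ] <- d
  }
  list(frames = dff, dt_ms = s$dt_ms, preexposure_s = s$preexposure_s,
       units = "dff", valid = valid)
}

# Butterworth lowpass factored into bilinear-transformed biquad sections:
# the direct polynomial form is badly conditioned at very low normalized
# cutoffs (poles clustered near z = 1), the cascade is not.
butter_biquads <- function(order, Wn) {
  if (order %% 2L != 0L)
    stop_config("order", "must be even (cascaded biquad sections)")
  wa <- tan(pi * Wn / 2)
  lapply(seq_len(order / 2), function(k) {
    theta <- pi * (2 * k + order - 1) / (2 * order)
    s <- wa * complex(real = cos(theta), imaginary = sin(theta))
    zp <- (1 + s) / (1 - s)
    a <- c(1, -2 * Re(zp), Mod(zp)^2)
    b <- c(1, 2, 1)
    b <- b * sum(a) / sum(b)   # unity DC gain
    signal::Arma(b, a)
  })
}

# Lowpass a slow trace without boundary bias: extrapolate both ends with a
# quadratic fit before zero-phase (forward-backward) filtering, then trim.
# The maximally flat Butterworth passband leaves polynomial trends
# untouched away from the boundaries; the padding is sized so the edge
# transients decay below double precision before reaching the trace.
lowpass_trace <- function(trace, fs_hz, cutoff_hz, order) {
  secs <- butter_biquads(order, cutoff_hz / (fs_hz / 2))
  n <- length(trace)
  pad <- ceiling(15 * fs_hz / cutoff_hz)
  m <- max(3L, ceiling(n / 2))
  fit_end <- function(idx) {
    co <- stats::lm.fit(cbind(1, idx, idx^2), trace[idx])$coefficients
    function(t) co[1] + co[2] * t + co[3] * t^2
  }
  fL <- fit_end(seq_len(m))
  fR <- fit_end((n - m + 1L):n)
  padded <- c(fL(seq(1 - pad, 0)), trace, fR(seq(n + 1, n + pad)))
  for (sec in secs) padded <- signal::filtfilt(sec, padded)
  padded[(pad + 1):(pad + n)]
}

#' Fit the photobleaching trend of a dF/F sequence
#'
#' Computes the mean dF/F trace over a region of interest, lowpasses it with
#' a zero-phase Butterworth filter (2.5 Hz, order 4 by default), and fits a
#' second-degree polynomial in absolute exposure time (the time axis is
#' offset by the pre-exposure lead so the decay curvature is comparable
#' across trials with different shutter-open lead times).
#'
#' @param seq dF/F sequence (>= 10 frames, sampling rate above 5 Hz).
#' @param roi logical H x W mask (non-empty) over which the trace is
#'   averaged.
#' @param cutoff_hz,order Butterworth lowpass settings.
#' @return a `bleach_fit`: `poly` `(a, b, c)` such that the trend is
#'   `a t^2 + b t + c` (t in seconds of absolute time), `filter`, `t_abs_s`,
#'   `roi_trace` (fitted trend at the sequence's frames), `raw_trace`.
#' @export
fit_bleach <- function(seq, roi, cutoff_hz = 2.5, order = 4L) {
  s <- as_fluo_seq(seq, units = "dff")
  T <- dim(s$frames)[1]
  if (T < 10L) stop("sequence too short to fit a bleach trend (need >= 10)",
                    call. = FALSE)
  fs <- 1000 / s$dt_ms
  if (fs <= 5) stop("sampling rate must exceed 5 Hz", call. = FALSE)
  if (cutoff_hz >= fs / 2)
    stop_config("cutoff_hz", "must be below the Nyquist frequency")
  if (missing(roi) || is.null(roi)) roi <- matrix(TRUE, dim(s$frames)[2],
                                                  dim(s$frames)[3])
  if (!any(roi)) stop("empty ROI", call. = FALSE)
  ridx <- which(roi)
  trace <- vapply(seq_len(T), function(t) {
    fr <- s$frames[t, , ]
    mean(fr[ridx], na.rm = TRUE)
  }, numeric(1))
  filt <- lowpass_trace(trace, fs, cutoff_hz, order)
  t_abs <- seq_times_s(s)
  co <- stats::lm.fit(cbind(1, t_abs, t_abs^2), filt)$coefficients
  poly <- c(a = unname(co[3]), b = unname(co[2]), c = unname(co[1]))
  structure(list(poly = poly,
                 filter = list(cutoff_hz = cutoff_hz, order = order),
                 t_abs_s = t_abs,
                 roi_trace = poly[1] * t_abs^2 + poly[2] * t_abs + poly[3],
                 raw_trace = trace),
            class = "bleach_fit")
}

#' Subtract a fitted bleach trend from a dF/F sequence
#'
#' The fitted scalar trend, evaluated on the sequence's absolute time axis,
#' is subtracted from every pixel's time series; a fast embedded transient is
#' untouched because the subtracted trend is a slow quadratic.
#'
#' @param seq dF/F sequence.
#' @param fit a [fit_bleach()] result (or a `poly` 3-vector `(a, b, c)`).
#' @return the corrected sequence.
#' @export
correct_bleach <- function(seq, fit) {
  s <- as_fluo_seq(seq, units = "dff")
  poly <- if (inherits(fit, "bleach_fit")) fit$poly else as.numeric(fit)
  if (length(poly) != 3L || any(!is.finite(poly)))
    stop("bleach fit must supply quadratic coefficients (a, b, c)",
         call. = FALSE)
  t_abs <- seq_times_s(s)
  trend <- poly[1] * t_abs^2 + poly[2] * t_abs + poly[3]
  for (t in seq_along(trend)) s$frames[t, , ] <- s$frames[t, , ] - trend[t]
  s
}

#' Regression of bleach severity on pre-exposure time
#'
#' The natural log of the leading quadratic coefficient `a` of each trial's
#' bleach fit is regressed (second-degree polynomial) on the trial's
#' pre-exposure time: longer shutter-open lead times put the acquisition past
#' the steep phase of the dye decay, giving smaller `a`.
#'
#' @param fits list of [fit_bleach()] results (or numeric vector of `a`
#'   coefficients).
#' @param preexposure_s pre-exposure time of each trial, seconds.
#' @return list: `coefficients` (intercept, linear, quadratic), `model` (the
#'   `lm`), `predict` — function of pre-exposure time returning `ln(a)` with
#'   a `confidence` attribute (lower/upper band).
#' @export
bleach_vs_preexposure <- function(fits, preexposure_s) {
  a <- if (is.numeric(fits)) fits
  else vapply(fits, function(f) unname(f$poly[1]), numeric(1))
  if (length(a) != length(preexposure_s))
    stop("one pre-exposure time per fit is required", call. = FALSE)
  pos <- a > 0
  if (any(!pos))
    warning(sprintf("%d trial(s) with a <= 0 excluded from the regression",
                    sum(!pos)))
  a <- a[pos]; tpre <- preexposure_s[pos]
  if (length(a) < 3L)
    stop("need at least 3 trials with a > 0", call. = FALSE)
  if (length(unique(tpre)) < 3L)
    stop("rank-deficient design: need at least 3 distinct pre-exposure times",
         call. = FALSE)
  df <- data.frame(lna = log(a), tpre = tpre)
  model <- stats::lm(lna ~ tpre + I(tpre^2), data = df)
  pred <- function(tpre_new) {
    p <- stats::predict(model, newdata = data.frame(tpre = tpre_new),
                        interval = "confidence")
    out <- p[, "fit"]
    attr(out, "confidence") <- p[, c("lwr", "upr"), drop = FALSE]
    out
  }
  list(coefficients = unname(stats::coef(model)), model = model,
       predict = pred)
}

#' Patterned-noise frequency mask
#'
#' @param freqs n x 2 matrix (or 2-vector) of spatial frequencies
#'   `(fx, fy)` in cycles/pixel to null; the conjugate (negated) frequencies
#'   are closed over automatically so filtered frames stay real. DC is not
#'   allowed.
#' @return a `noise_mask` object.
#' @export
noise_mask <- function(freqs) {
  f <- matrix(as.numeric(freqs), ncol = 2L)
  if (any(!is.finite(f))) stop_config("freqs", "must be finite")
  if (any(rowSums(abs(f)) == 0))
    stop("DC must not be in the noise mask", call. = FALSE)
  structure(list(freqs = f), class = "noise_mask")
}

# integer bin indices (1-based, R fft layout) of a frequency pair for an
# H x W frame, plus the conjugate bin
mask_bins <- function(mask, h, w) {
  f <- mask$freqs
  kx <- round(f[, 1] * w) %% w
  ky <- round(f[, 2] * h) %% h
  if (any(kx == 0 & ky == 0))
    stop("DC must not be in the noise mask", call. = FALSE)
  rows <- c(ky, (h - ky) %% h) + 1L
  cols <- c(kx, (w - kx) %% w) + 1L
  unique(cbind(rows, cols))
}

#' Remove patterned (moire) noise by Fourier-bin nulling
#'
#' Per frame: 2-D FFT, set the masked frequency bins and their conjugates to
#' zero, inverse FFT. The operation is exact: masked-bin amplitude drops to
#' numerical zero while every other bin is untouched, and the output is real.
#'
#' @param seq a sequence list, T x H x W array, or single H x W matrix.
#' @param mask a [noise_mask()].
#' @return the filtered input, same type as given.
#' @export
remove_patterned_noise <- function(seq, mask) {
  stopifnot(inherits(mask, "noise_mask"))
  filter_frame <- function(fr) {
    bins <- mask_bins(mask, nrow(fr), ncol(fr))
    F <- stats::fft(fr)
    F[bins] <- 0
    Re(stats::fft(F, inverse = TRUE)) / length(fr)
  }
  if (is.matrix(seq)) return(filter_frame(seq))
  s <- as_fluo_seq(seq)
  for (t in seq_len(dim(s$frames)[1]))
    s$frames[t, , ] <- filter_frame(s$frames[t, , ])
  if (is.array(seq) && !is.list(seq)) s$frames else s
}

#' Spatial Gaussian smoothing
#'
#' Per-frame convolution with a normalized truncated Gaussian kernel
#' (default 5 x 5), with replicated edges so constant frames pass through
#' unchanged.
#'
#' @param seq sequence list, T x H x W array, or single matrix.
#' @param kernel_px odd kernel size in pixels.
#' @param sigma_px Gaussian sigma; defaults to `kernel_px / 5`.
#' @return the smoothed input, same type as given.
#' @export
spatial_smooth <- function(seq, kernel_px = 5L, sigma_px = kernel_px / 5) {
  check_scalar(kernel_px, "kernel_px", lower = 1, integer = TRUE)
  if (kernel_px %% 2L == 0L)
    stop_config("kernel_px", "must be odd")
  check_scalar(sigma_px, "sigma_px", lower = 1e-9)
  r <- (kernel_px - 1L) / 2L
  g1 <- exp(-(-r:r)^2 / (2 * sigma_px^2))
  K <- outer(g1, g1); K <- K / sum(K)
  smooth_frame <- function(fr) {
    h <- nrow(fr); w <- ncol(fr)
    if (r == 0) return(fr)
    pr <- fr[c(rep(1, r), seq_len(h), rep(h, r)),
             c(rep(1, r), seq_len(w), rep(w, r))]
    out <- matrix(0, h, w)
    for (i in seq_len(kernel_px)) for (j in seq_len(kernel_px))
      out <- out + K[i, j] * pr[(i):(i + h - 1L), (j):(j + w - 1L)]
    out
  }
  if (is.matrix(seq)) return(smooth_frame(seq))
  s <- as_fluo_seq(seq)
  for (t in seq_len(dim(s$frames)[1]))
    s$frames[t, , ] <- smooth_frame(s$frames[t, , ])
  if (is.array(seq) && !is.list(seq)) s$frames else s
}
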