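# Shared validation and small-geometry helpers.

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg),
       call. = FALSE)
}

check_scalar <- function(x, field, lower = -Inf, upper = Inf,
                         integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_config(field, "must be a finite numeric scalar")
  if (integer && x != round(x))
    stop_config(field, "must be an integer")
  if (x < lower) stop_config(field, sprintf("must be >= %g", lower))
  if (x > upper) stop_config(field, sprintf("must be <= %g", upper))
  invisible(x)
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# 2x2 counter-clockwise rotation matrix, angle in degrees
rot2 <- function(theta_deg) {
  a <- deg2rad(theta_deg)
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2L, 2L)
}

# principal value in (-180, 180]
wrap180 <- function(deg) {
  w <- (deg + 180) %% 360 - 180
  w[w == -180] <- 180
  w
}

`%||%` <- function(a, b) if (is.null(a)) b else a
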