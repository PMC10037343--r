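# Shared fixtures (generated in code, cached per session) and independent
# oracles used to freeze expected values.

.fixture_cache <- new.env(parent = emptyenv())

fixture_scene <- function(sensor_px = 100L, n_broken = 3L, seed = 11L) {
  key <- sprintf("scene_%d_%d_%d", sensor_px, n_broken, seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- make_bundle_scene(
      scene_config(sensor_px = sensor_px, n_broken_patches = n_broken,
                   rng_seed = seed))
  .fixture_cache[[key]]
}

# Independent closed-form 2-D rigid fit (complex-number formulation, no SVD):
# the optimal rotation maps a-cloud onto b-cloud via the argument of the
# cross-covariance expressed as complex numbers.
procrustes_oracle <- function(a, b) {
  za <- complex(real = a[, 1], imaginary = a[, 2])
  zb <- complex(real = b[, 1], imaginary = b[, 2])
  za0 <- za - mean(za); zb0 <- zb - mean(zb)
  theta <- Arg(sum(zb0 * Conj(za0)))
  t <- mean(zb) - exp(1i * theta) * mean(za)
  list(theta_deg = theta * 180 / pi, tx = Re(t), ty = Im(t))
}

# Brute-force dead-band (pin-in-slot) backlash oracle: the commanded slot
# advances one microstep at a time and pushes the output pin only when the
# gap is fully taken up.
deadband_oracle <- function(moves, backlash) {
  # output pin rides in the slot [commanded, commanded + backlash]
  commanded <- 0; output <- 0
  for (mv in moves) {
    step <- sign(mv)
    for (k in seq_len(abs(mv))) {
      commanded <- commanded + step
      if (output < commanded) output <- commanded
      if (output > commanded + backlash) output <- commanded + backlash
    }
  }
  list(commanded = commanded, output = output)
}

# expanding-disk ROI helper
disk_mask <- function(n, center = (n + 1) / 2, radius = n / 3) {
  g <- expand.grid(r = seq_len(n), c = seq_len(n))
  matrix((g$r - center)^2 + (g$c - center)^2 <= radius^2, n, n)
}
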