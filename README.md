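# fibrojoint

Computational toolkit for a **motorized optical rotary joint for
fibroscopy** — imaging a freely moving animal's brain through a coherent
fiber bundle whose proximal end is actively rotated to follow the animal's
head yaw, so the bundle never accumulates torsion.

The package is aimed at researchers building or evaluating such active
joints. It implements, around a fully simulated optical/mechanical bench:

- **Head-orientation tracking** from 9-DoF IMU streams with the Madgwick
  gradient-descent fusion filter (`madgwick_filter()`, hard-iron
  calibration, yaw unwrapping).
- **Joint simulation**: a 400-step x8-microstepping motor behind a 1:3 belt
  (9600 microsteps per revolution), dead-band backlash, anti-backlash
  locking at the optimal reference orientation (OREF), and the three
  operating modes — HR (lock during each acquisition sequence), SR
  (semi-continuous, lock only during exposures, register offline), and
  hybrid (locked with one-revolution unwinds past 360° of torsion).
- **Motor-keyed rigid registration**: keypoint matching + RANSAC/Procrustes
  estimation, a calibrated look-up table of rotation/translation offsets
  keyed by motor angle, one-step bicubic resampling, and the accuracy
  metrics of the characterization protocol (translation in µm, rotation in
  arcmin, fraction of pixels within ±0.25% of the intensity range).
- **VSD signal chain**: ΔF/F₀ (three-frame F₀), photobleaching correction by
  a 2.5-Hz low-passed quadratic fit, ln(a)-vs-pre-exposure regression,
  Fourier notch removal of patterned (moiré) noise, 5×5 Gaussian smoothing.
- **Behavior metrics**: time-weighted distribution of cumulated revolutions
  with its D9/Q2 quantiles, mean angular velocity, mean displacement, and
  paired condition tests.
- **Synthetic-data generators** for all of the above with known ground
  truth (bundle scenes, captures under eccentric rotation, VSD sequences,
  IMU streams, arena trajectories).

## The core quantities

One output-shaft revolution subdivides into
`physical_steps × microstepping × gear = 400 × 8 × 3 = 9600` microsteps. A
2.5-mm bundle field on a 100-px sensor samples 25 µm/px, so a registration
error of t µm biases `t/p` of each pixel's area for an edge-parallel
translation and `1 − (1 − t/(p√2))²` along the diagonal — 4% and ≈5.6% at
t = 1 µm. Registration between a capture at motor angle φ and the OREF
reference is the rigid map `x ↦ R(−φ)x + (I − R(−φ))c`, where `c` is the
rotation-axis eccentricity: the translations trace a circle of chords
`2|c| sin(φ/2)`, which the LUT calibration recovers.

## Worked example

```r
library(fibrojoint)

# simulated bench: textured bundle scene, noisy sensor, eccentric axis
scene <- make_bundle_scene(scene_config(n_broken_patches = 3L, rng_seed = 11L))
cap   <- capture_config(ecc_um = c(50, 20), noise_sd_counts = 60,
                        moire = c(0.23, 0.31, 0.7, 40))

# hardware-registration accuracy protocol: random excursion + anti-backlash
# re-lock before each of 10 captures, compared to the OREF reference
report <- simulate_characterization(scene, cap,
                                    motor_config(backlash_usteps = 2L),
                                    "HR", n_images = 10L, seed = 1)
print(report)
#> HR characterization (10 images): median translation 0.296 um,
#> median rotation 0.228 arcmin, median frac within 0.25%: 78.0%

# IMU-driven yaw tracking on a noiseless 50-Hz stream
imu <- make_imu_stream(function(t) 120 * sin(0.4 * t), 12, imu_sim_config())
est <- madgwick_filter(imu)
err <- abs(unwrap_yaw(est$yaw_deg) - 120 * sin(0.4 * imu$t_s))
max(err[imu$t_s > 5])
#> 0.032  # degrees
```

The report's medians say that after motor excursions the re-locked image
lands within a third of a micrometer (about 1/80 px) and a quarter of an
arcminute of the reference, and 78% of pixels stay within ±0.25% of the
16-bit intensity range — the hardware-registration regime where frames are
usable without any software resampling.

A thin command-line front end over the same functions is available as
`scripts/fibrojoint` (subcommands `simulate-session`, `calibrate-lut`,
`register`, `characterize`, `process-vsd`, `behavior-metrics`).

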