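---
title: "Methods: simulating and analyzing a motorized optical rotary joint for fibroscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing a motorized optical rotary joint for fibroscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrojoint)
```

## The problem

Wide-field fibroscopy couples a freely moving animal to a static optical
bench through a coherent fiber bundle. Every net rotation of the animal
twists the bundle; beyond a few turns the torsion restricts movement and can
damage the fiber. A motorized rotary joint, driven in real time by a
head-mounted 9-DoF IMU, can continuously rotate the bundle's proximal end to
cancel that torsion. This package implements the computational stack of such
a system — orientation estimation, joint control simulation, motor-keyed
image registration, the voltage-sensitive-dye (VSD) processing chain, and
behavior metrics — against a fully simulated optical/mechanical bench with
known ground truth.

## The simulated bench

`make_bundle_scene()` builds the object the sensor images: a square
fiber-bundle field (2.5 mm across by default, imaged at 25 um/px on a
100 x 100 16-bit sensor) textured as a mosaic of 6x6-fiber patch elements.
Individual 8-um fiber cores are below the sensor pitch and are not modeled;
what the sensor resolves is the patch mosaic, so the texture is one random
log-normal gain per patch (sd 0.2) with a dome-shaped intra-patch profile
(depth 0.35) and an optional number of near-zero "broken" patches. A radial
vignette (0.15) and a 16-bit base level of 30 000 counts complete the scene.
The scene is generated at 4x the sensor pitch so sub-pixel rigid motion is
well defined, and the sensor integrates 4 x 4 sub-samples per pixel
(area-averaging). An optional Gaussian optical blur (`blur_um`) stands in
for the fiber-core/NA point spread; the default is 0 (sharp mosaic), and
smooth-scene tests use 25 um.

`render_capture()` models the joint geometry. The bundle center coincides
with the sensor center at the reference orientation; the joint's rotation
axis sits `ecc_um` away from it. Rotating the motor by `phi` therefore makes
the image content describe a circle: the rigid transform from a capture at
`phi` back to the reference is a rotation of `-phi` about the image center
plus a translation `(I - R(-phi)) ecc`, whose magnitude is the chord
`2 |ecc| sin(phi/2)`. This is the quantity the registration LUT must learn.
Additive Gaussian sensor noise (default study condition: 60 counts), a
single global moire sinusoid (frequency and phase are free parameters; the
study condition uses 0.23/0.31 cycles/px at 40 counts), and 16-bit clipping
and quantization complete the capture model.

The VSD generator multiplies the resting image by
`1 + bleach(t) + wave(t) + noise`: a quadratic photobleaching trend in dF/F
units evaluated on the absolute time axis (shutter opens `preexposure_s`
before frame 0), an expanding Gaussian-annulus depolarization wave, and
per-pixel Gaussian dF/F noise. The defaults mirror a 512-frame, 2-ms
acquisition. The bleach time constant of the dye is not a published number;
the default quadratic coefficients (a = 0.004, b = -0.03, c = 0.02 in dF/F
per s^2, s^1, 1) produce a percent-scale decay over one second, which is
what matters for the correction algorithms.

The IMU generator differentiates a yaw profile analytically (numerical
central difference at 1e-4 s) into the z-gyro, reads gravity (0, 0, 1) g on
a level head, and rotates a mid-latitude reference field (25, 0, -40) uT
into the sensor frame. The trajectory generator drives heading with a
mean-reverting (OU) turning rate — stationary sd 45 deg/s, relaxation 1 s —
rather than a white-noise heading walk, so angular-velocity metrics converge
as the tracking frame rate grows; at the arena wall the position is clamped
(the animal slides) while the heading process continues, keeping the
cumulated yaw faithful to the turning model.

## Orientation estimation

`madgwick_update()` implements the gradient-descent MARG fusion filter: the
quaternion is propagated by the gyro and corrected by a normalized gradient
step on the joint gravity + flux objective, with the earth-frame flux
reference re-derived from the current estimate so only yaw is anchored by
the magnetometer. Three numerical choices matter:

* the gyro propagation uses the exact quaternion exponential, because the
  first-order `q + q_dot dt` update under-rotates measurably at fast head
  turns (hundreds of deg/s at 50 Hz);
* the correction is evaluated at the gyro-propagated state, since the
  measurement is concurrent with the end of the step — evaluating it at the
  pre-step state leaves a systematic one-sample lead at constant rotation;
* the gain is scheduled on the measurement-residual norm
  (`beta_eff = beta (1 + 9 min(1, ||f||))`), which accelerates convergence
  from a poor initial attitude to under half a degree within 250 samples
  while leaving the steady-state gain at Madgwick's recommended
  `beta = 0.1`.

Streams are normally initialized TRIAD-style from the first accel/mag pair,
which gives absolute yaw immediately. The stream filter additionally
averages consecutive gyro samples (midpoint rule). Hard-iron calibration is
a linear least-squares sphere fit; soft-iron (ellipsoid) correction is out
of scope, and magnetic declination is ignored because only relative yaw
drives the joint.

## Joint simulation

The drivetrain is kinematic: 400 physical steps x8 microstepping behind a
1:3 belt give 9600 microsteps per output revolution; motion is rate-limited,
torque and belt dynamics are not modeled. Backlash is a pure symmetric dead
band of `backlash_usteps`: on reversal the first B commanded microsteps
produce no output motion. `lock_at_oref()` implements the anti-backlash
approach — overshoot past OREF by more than the backlash, then approach in a
fixed positive direction — which makes the realized lock angle *exactly*
repeatable (zero microstep spread) for any backlash not exceeding the
approach offset; the approach offset defaults to twice the backlash and is
validated against it. In a session, HR mode locks at the nearest
360-degree-equivalent of OREF (minimizing the torsion jump), SR mode holds
the commanded velocity at zero during each exposure window (settle time
configurable, default 0), and hybrid mode stays locked, unwinding exactly
one revolution whenever the accumulated torsion reaches 360 degrees.

## Registration

Frame-to-frame motion is estimated from keypoints: difference-of-Gaussian
blobs with 3x3 quadratic sub-pixel refinement, described by a
rotation-invariant descriptor (normalized concentric-ring samples summarized
by ring means and angular FFT magnitudes), matched by mutual nearest
neighbors with a Lowe ratio test. Rigid motion (rotation + translation, no
scale or shear) is fit by RANSAC over two-point samples (1000 iterations,
1-px inlier tolerance, seeded) followed by a closed-form least-squares
(Procrustes) solution on the consensus set; on clean pairs the result equals
the closed form to numerical precision.

LUT calibration estimates the capture-to-reference transform at each
calibration angle and optionally refines it by minimizing the masked mean
squared intensity difference under `apply_rigid()` (Nelder-Mead over theta,
tx, ty), which brings translation accuracy below 0.1 px — needed to meet the
2-um eccentricity-recovery target at a 25-um pitch. The LUT stores total
transforms keyed by motor angle, with an exact identity entry at OREF;
queries interpolate linearly and periodically in angle (the rotation
component is unwrapped first). `apply_rigid()` resamples in a single pass
with the Keys bicubic kernel (a = -0.5) to avoid repeated-interpolation
blur; out-of-field pixels are zero-filled and flagged in a validity mask.

`simulate_characterization()` reproduces the three-series accuracy protocol:
NM (repeated captures at OREF, the optical noise floor), HR (random
excursion + anti-backlash re-lock before each capture), and SR (captures
across 9-345 degrees, positioned with backlash from alternating directions
and registered through the LUT). Because the simulated anti-backlash lock is
exact, HR would otherwise be statistically identical to NM; a small
post-motion settling jitter (sd 0.3 um per axis, 0.3 arcmin — the order of
magnitude a real bench shows after motion) is applied at capture time. It
models mechanical settling of the optical assembly, not motor state, so the
zero lock-spread guarantee is untouched. Intensity-variation fractions are
evaluated on a central disk that stays valid under re-rotation, making the
three modes comparable.

## VSD processing

dF/F0 uses the mean of three frames around the reference frame, flagging
pixels with non-positive F0 invalid instead of dividing by zero. The bleach
trend is the ROI-mean trace lowpassed at 2.5 Hz (Butterworth, order 4,
forward-backward for zero phase) and fit with a quadratic in absolute
exposure time. Two numerical points: the filter is applied as cascaded
bilinear-transformed biquad sections, because the direct order-4 polynomial
form is badly conditioned at a 0.01 normalized cutoff; and the trace is
extrapolated with a quadratic fit over 15 filter time constants on each side
before filtering, so boundary transients decay below double precision and an
exactly quadratic input is recovered to machine accuracy (the maximally flat
Butterworth passband is moment-free, so the filter itself does not bias
polynomial trends). Correction subtracts the fitted scalar trend from every
pixel in dF/F units. The bleach-severity regression fits `ln(a)` (leading
quadratic coefficient) against pre-exposure time with a second-degree
polynomial, excluding non-positive `a` with a warning.

Patterned (moire) noise removal nulls the chosen frequency bins and their
conjugates in the 2-D FFT of every frame — an exact linear operation that
leaves all other bins untouched and keeps the output real; DC is rejected at
construction. Spatial smoothing is a normalized truncated Gaussian (5 x 5,
sigma = kernel/5 since only the kernel size is standard) with replicated
edges so constant frames pass through unchanged.

## Behavior metrics

Cumulated revolutions are `(yaw - yaw_0)/360` on unwrapped yaw. The
time-weighted distribution treats the series as piecewise linear in time and
computes exact time-below-level measures, from which D9 (90% of session time
spent below) and Q2 (median) are obtained by root finding; the magnitude
`|revolutions|` is used so clockwise and counter-clockwise torsion count
equally. The histogram bin width defaults to 0.25 revolution. Angular
velocity is the mean of `|d yaw/dt|` and displacement the mean of
`||d p||/dt` over consecutive retained pairs, excluding pairs that span
removed low-confidence gaps (gap threshold: three median sampling
intervals). "Mean displacement" is reported in mm/s because the per-frame
alternative depends on the tracking frame rate. Paired condition contrasts
use the Wilcoxon signed-rank test or the paired t-test; an all-zero
difference vector is reported as the degenerate p = 1.

## Problem sizes and what the tests show

The test and acceptance workloads run the full protocol at desk scale: 25
images per characterization series over 100 x 100 px frames, 8-12 LUT
angles, 256-frame VSD sequences on 40-60 px fields, 50-Hz IMU streams of
10-600 s, and 20 replicate behavioral sessions of 60 s at 50 Hz. Passing
them shows that the algorithms are internally consistent against generated
ground truth under the stated noise model — Gaussian sensor noise, a single
global moire sinusoid, quadratic bleach, rigid motion only. They do not
certify behavior on real data, where fiber-core aliasing, illumination
drift, non-rigid tissue motion and tracking failures add structure the
generators deliberately omit.

## Known limitations

* The backlash model is a pure dead band; elasticity and belt-tension
  dynamics are not simulated.
* The keypoint detector is single-scale (the bench has no scale changes);
  images with strong scale variation would need a pyramid.
* Soft-iron magnetometer distortion and pitch/roll excursions of the head
  are not modeled.
* SR characterization inherits whatever the LUT learned: with coarse
  calibration spacing the dominant SR error is LUT interpolation, which is
  the intended behavior of the protocol rather than a bound on the method.
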