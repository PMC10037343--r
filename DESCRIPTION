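Package: fibrojoint
Title: Simulation and Analysis of a Motorized Optical Rotary Joint for
    Fibroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computational toolkit around a motorized optical rotary joint
    used for wide-field fibroscopy in freely moving animals. Provides
    IMU-based head-orientation tracking (Madgwick sensor fusion), a kinematic
    simulation of the stepper-driven joint with backlash and anti-backlash
    locking in its three operating modes, motor-angle-keyed rigid image
    registration with LUT calibration, registration-accuracy
    characterization, a voltage-sensitive-dye image-processing chain
    (dF/F0, photobleaching correction, Fourier notch filtering, spatial
    smoothing), freely-moving behavior metrics, and synthetic-data
    generators with known ground truth for all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
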