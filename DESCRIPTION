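Package: peckkin
Title: Kinematics and Mixed-Model Analysis of Avian Pecking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the kinematics of avian pecking recorded as
    2-D marker trajectories of the head and bill tips. Provides zero-phase
    Butterworth smoothing, detection of head fixation and bill-grasping
    onset/offset from the aperture profile, per-peck kinematic parameters
    (grasping-onset time, movement distance, mean velocity, mean
    acceleration), random-intercept binomial and Gaussian mixed models fitted
    by adaptive Gauss-Hermite quadrature and profiled likelihood,
    likelihood-ratio tests, overdispersion checks, per-phase confidence
    intervals and marginal/conditional R-squared, plus a ground-truth
    simulator of pecking with artificial bill extensions for validating the
    whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    car
Config/testthat/edition: 3
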