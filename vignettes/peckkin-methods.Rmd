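---
title: "Pecking kinematics and mixed models: methods and design choices"
author: "peckkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pecking kinematics and mixed models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peckkin)
```

## The problem

Avian pecking is a two-component feeding movement: the head reaches toward
a target food item, and the bill grasps it. A classical way to probe how
this movement is controlled is to perturb the effector — here, by gluing
an artificial extension onto the bill — and to ask whether, and how, the
bird adjusts. `peckkin` implements the full quantitative chain for such
experiments: from 2-D marker trajectories of the head and the two bill
tips (sagittal view, 300 frames/s, coordinates in cm with the target food
at the origin) to per-peck events, kinematic parameters, and the mixed
models that compare experimental phases.

The experimental design the package assumes has seven phases with
`control` as the reference level: a normal-bill control phase, the first
bill-extension session `S1`, grouped extension sessions `S2-4`, `S5-7`
and `S8-10`, an extension `removal` session, and a `follow-up` control
phase a week later. Two species presets encode the contrast of interest:
pigeon-like behaviour (a persistent deficit under the extension plus a
motor *after-effect* — an advanced grasping onset — on removal) and
crow-like behaviour (a transient deficit in `S1` only, compensated by
initiating the reach closer to the target, with no after-effect).

## Event definitions and kinematic parameters

A peck runs from **head fixation** — a rapid standstill of the head in
front of the target — to **grasping offset**. The operational
definitions, applied to tracks smoothed with a 5 Hz zero-phase
Butterworth low-pass filter:

* *Bill aperture*: Euclidean distance between the upper and lower
  bill-tip markers, per frame.
* *Fixation*: first frame of the last interval of at least
  `min_still_frames` consecutive frames (default 10, i.e. 33 ms) before
  the reach's global speed peak in which the head's instantaneous speed
  stays below `speed_threshold` (default 2 cm/s). The literature gives no
  canonical numeric standstill criterion, so both values are explicit,
  configurable declarations.
* *Grasping onset*: the first frame at which the aperture has opened by
  20% of the maximum grasping aperture. Because the closed bill has a
  nonzero marker separation, the default measures the opening relative to
  the aperture baseline at fixation; an absolute-of-maximum variant is a
  config switch (`onset_rule = "absolute"`).
* *Grasping offset*: the frame of minimum aperture after the aperture
  maximum. The offset aperture is typically nonzero because the bill
  holds the food.
* The four per-peck parameters entering the models: grasping-onset time
  (s from fixation), movement distance (cm), mean velocity (cm/s) and
  mean acceleration (cm/s²). Velocity and acceleration are means of
  frame-wise finite differences on the fixation-to-onset window, so two
  identities hold exactly: mean velocity × window duration = movement
  distance over that window, and mean acceleration telescopes to
  (v_last − v_first)/duration.

**The movement-distance window.** Movement distance is measured over the
whole peck (fixation to offset) by default, while velocity and
acceleration use the fixation-to-onset window. This asymmetry is
deliberate. If distance is also truncated at onset, it becomes an exact
mechanical mediator of grasp timing — a peck that opens its bill later
has, by construction, travelled farther at onset — and a covariate-
adjusted phase model of onset time can no longer see any phase effect:
the covariate absorbs it entirely. Measured over the full peck, distance
is a pure reach-extent measure (how far the head was from the food at
fixation), which is what a covariate in an onset model should be. The
truncated variant remains available (`distance_end = "onset"`).

Pecks are excluded, never silently dropped: any marker gap inside the
fixation-to-offset window (the analogue of markers leaving the video
frame), a failed detector, or a too-short window yields a record with
`retained = FALSE` and a reason, so exclusion accounting always conserves
pecks.

## Smoothing

The 5 Hz low-pass cutoff is the field's standard for pecking kinematics
and is applied as a 4th-order Butterworth forward and backward (zero
phase), which squares the magnitude response — the effective amplitude
gain is $1/(1+(f/f_c)^8)$ — and avoids any phase lag that would bias
event times. Two implementation details matter more than they look:

* **Initial conditions.** Each pass starts from the filter's steady-state
  response scaled to the first sample, so a constant series is reproduced
  to machine precision (unit DC gain), rather than ramping in from zero.
* **Edge padding.** The series is extended by *symmetric* (even)
  reflection. Odd (point-mirrored) reflection, a common default,
  amplifies measurement noise near the boundaries — we measured a
  5.6-fold inflation of noise s.d. at the first frame — which corrupts
  exactly the two quantities that live at the series edge: fixation
  detection and the aperture baseline. Marker tracks begin and end near
  rest, where even reflection is also the signal-faithful choice.

For batch extraction the aperture baseline is averaged over 10 frames
from fixation and the 20% threshold must be held for 3 consecutive
frames; both guards exist because a single noisy frame at the series edge
otherwise mis-sets the onset threshold. The primitive
`detect_grasp_events()` keeps the literal single-frame baseline as its
default.

## The mixed models

Pecking **success** is modelled with a binomial GLMM (logit link):
outcome ~ phase, with a per-individual random intercept. The marginal
likelihood integrates each bird's intercept out of the conditional
Bernoulli likelihood with *adaptive Gauss–Hermite quadrature*: the
quadrature nodes are recentred at each group's conditional mode and
rescaled by the local curvature (a Laplace rescaling), so 15 nodes
(default) integrate accurately even for extreme groups; the package's
tests verify agreement with brute-force trapezoidal integration to 1e-6
per group and stability of the estimates from 7 to 25 nodes.

**Grasping-onset time** is modelled with a Gaussian LMM: onset ~ phase +
distance + acceleration, individual as random intercept. Velocity is
excluded because it is collinear with distance (their ratio is roughly
the inverse reach duration). With a single grouping factor the fit
profiles the fixed effects and residual variance out in closed form
(Woodbury identity per group) and optimises only the variance ratio
θ = σ²ᵤ/σ²ₑ in one dimension; a boundary optimum is reported as σ²ᵤ = 0.
ML is used for every fit entering a likelihood-ratio test; REML is
available for variance reporting.

Inference follows the field's standard recipe:

* **Likelihood-ratio tests**, term-wise in the type-II style (each term
  dropped from the model, main effects tested without their
  interactions). The seven phase levels give 6 degrees of freedom under
  treatment coding.
* **Overdispersion**: Pearson χ² at conditional fitted values (random
  intercepts at their modes) divided by residual degrees of freedom,
  charging one parameter per fixed effect and one per group; values near
  1 support the binomial variance assumption. Per-observation Bernoulli
  residuals are the default; an aggregated binomial-cell variant (with
  cell-based df) is the config switch that can actually *detect*
  unmodelled heterogeneity, since per-observation Pearson residuals on
  binary data are nearly insensitive to it.
* **Per-phase 95% CIs**: Wald intervals of the fixed-effect estimate for
  each phase at the observed covariate means, flagged against control by
  interval non-overlap — the graphical procedure of comparing each
  phase's error bar with the control band. Non-overlap of two 95% CIs is
  conservative (the null false-flag rate is well below 5%, which the
  tests confirm); a CI-of-difference variant is selectable.
* **Nakagawa–Schielzeth R²**: marginal = var(fixed predictor) over
  (fixed + random-intercept + residual) variance; conditional adds the
  random-intercept variance to the numerator. Population variances
  (n denominators) are used throughout so that the marginal R² equals the
  classical R² exactly when σ²ᵤ = 0. For the binomial-logit family the
  latent residual variance is π²/3.

**Small-sample caveat.** The study design has three birds per species.
Wald CIs that treat the random-intercept variance as known undercover at
that scale: our Monte-Carlo check shows ≈83% coverage of a nominal 95%
interval for the intercept with 3 groups (σᵤ = 0.5), against ≈93% with 30
groups. Conclusions that rest on between-individual generalisation from
three birds should be read with that in mind; the package reports the
machinery faithfully rather than hiding the issue.

## The synthetic-data generator

Every pipeline stage is validated against pecks with analytically known
ground truth. A simulated peck consists of:

* a pre-reach standstill of 0.3 s — the true fixation interval;
* a head reach along a gently curved arc (quadratic Bézier, bulge 8% of
  the chord, approach angle 40° above the horizontal) whose displacement
  follows the minimum-jerk profile s(τ) = P(10τ³ − 15τ⁴ + 6τ⁵), plus
  small smooth submovement ripples (three half-sine harmonics, amplitude
  0.008 of the path each). The head stops with the bill tip on the
  target, so the head path length is the fixation distance minus the
  (possibly extended) bill length;
* bill tips placed exactly one bill length from the head along the
  heading, split symmetrically so their separation equals the aperture —
  with the 1 cm extension on a 2.3 cm pigeon bill the tip-to-head
  distance is 3.3 cm in every frame, the worked morphometric example;
* a raised-cosine aperture pulse from the resting/offset aperture to the
  peak and back, triggered when half the head path is done; its 20%
  crossing (at a fraction acos(0.6)/2π ≈ 0.148 of the pulse) and its
  post-peak minimum are the true onset and offset;
* Bernoulli success from a logistic model with a per-individual random
  intercept (baseline 90% control success);
* i.i.d. Gaussian tracking noise, default σ = 0.05 cm per marker
  coordinate per frame.

Minimum-jerk reaches and raised-cosine pulses are modelling choices made
for smoothness and analytically known landmarks, not measured profiles.
Three generator parameters were fixed by explicit design calibration
against the package's own extraction contracts, before the test suite
was frozen:

* *Durations* (reach 0.7 s, grasp pulse 0.5 s): slow enough that the
  speed and aperture content lies essentially inside the 5 Hz passband.
  With faster profiles the mandated filter itself shifts the 20%
  crossing by several frames and no extractor could agree with the
  generator's analytic truth.
* *Grasp trigger at 50% of the path*: pins the onset near the speed
  peak, where a ±1-frame detection slip perturbs distance, velocity and
  acceleration each by ≲1.5%, keeping noise-free extraction within 2% of
  truth for every peck.
* *Timing variances* (trigger jitter 0.010 s per peck, 0.01 s per
  individual; reach-duration s.d. 0.015 s) and the submovement amplitude
  balance three requirements: truth recovery within 2%, onset recovery
  within ±2 frames in ≥95% of pecks at σ = 0.05 cm noise, and — because
  any timing shift propagates into the distance and acceleration
  covariates — enough covariate-independent speed variation that a
  conditional phase effect on onset remains estimable at all, as it
  plainly was in real data of this kind.

Phase presets encode the species contrast at the study's scale (three
birds; 974 pigeon pecks and 378 crow pecks over the seven phases, with
the per-phase counts of the original design). Effect sizes are anchored
to the published performance levels: control success ≈0.90 for both
species; pigeon extension phases ≈0.35 with onset delayed by 40 ms in S1
and 12 ms thereafter; pigeon removal ≈0.6 success with a 40 ms onset
*advance* (the after-effect); crow S1 success ≈0.3 — the deficit must be
of roughly this size for its detection from only 23 pecks, which the
original analysis reported, to be statistically reproducible — together
with a 1.5 cm shortening of the fixation distance through S5-7 and no
removal effect. The random-intercept s.d. on the success logit is 0.3.

**What the generator does not emulate.** Marker noise is i.i.d.
Gaussian, not the heavy-tailed, occasionally missing output of real video
tracking (gaps must be injected explicitly); the aperture pulse is
single-peaked with a fixed shape; success depends on phase and individual
but not on the realised kinematics of the peck; and the 2-D sagittal
projection is exact rather than a camera approximation. Passing tests
therefore demonstrate that the pipeline is correct under its stated
assumptions, not that those assumptions exhaust real pecking data.

## Numerical choices and degenerate inputs

* Ties in the aperture maximum resolve to the earliest frame; the 20%
  crossing takes the first qualifying frame with no sub-frame
  interpolation (the data are frame-resolution).
* The GLMM optimiser (`nlminb`, σᵤ bounded below by 0) uses a
  deterministic restart ladder; non-convergence is reported as
  `converged = FALSE`, and |β| > 15 raises a separation flag. At a
  σᵤ = 0 boundary the observed information is computed over the fixed
  effects only.
* A likelihood-ratio test of a model against itself returns statistic 0
  with df 0 and an undefined p-value rather than an error.
* Degenerate responses (all successes, constant onset) produce warnings
  and skipped fits in `control_phase_checks()`; a GLMM on them would not
  be estimable.
* Successive pecks at a seed array are treated as independent analysis
  units; `control_phase_checks()` fits the three control-phase models
  (success, onset, distance against target position × peck order) that
  justify this.

## Problem sizes used in the test suite

Simulation-backed tests run at deliberately chosen sizes: full
study-scale preset experiments (974 and 378 pecks) for the qualitative
species contrast; 200-peck batches for detection-robustness rates; 500
replicates for the null rejection rate of the LRT; 300 replicates for CI
coverage; 30 groups × 200 observations for GLMM parameter recovery.
Seeds are fixed in every simulation-facing test, and the acceptance
script derives all its randomness from its `--seed` argument.
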