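---
title: "Free-living gait analysis from a lumbar accelerometer: methods and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free-living gait analysis from a lumbar accelerometer: methods and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(freegait)
```

## The problem

A single tri-axial accelerometer worn at the lower back (L5, close to the
body's centre of mass) records continuously while a person goes about daily
life. From that stream we want: the periods when the person was actually
walking; the timing of each step within those periods; step length and
velocity from a biomechanical model; and, per 30 s window of walking, the
mean, variability (SD) and left/right asymmetry of five spatio-temporal
characteristics — step time, stance time, swing time, step length, step
velocity — organised into the four-domain mobility model (pace, rhythm,
variability, asymmetry). When interval context labels exist (terrain,
indoor/outdoor, single/dual task — typically coded from wearable video),
the windows are stratified by context and the most anomalous windows are
emitted as a review manifest for targeted video inspection, the use case
being fall-risk assessment where one wants to know whether an aberrant
step pattern was intrinsic (the person) or extrinsic (the environment).

## Signal chain

1. **Units and resampling.** Input CSV (`time, ax, ay, az`) is validated,
   placed on a uniform grid at the nominal rate (100 Hz by default) by
   linear interpolation, and converted between g and m/s² with the fixed
   standard-gravity constant 9.80665 (reproducibility over locale
   accuracy). If more than 1% of expected samples are missing, a warning is
   recorded in the run log.
2. **Walking bouts.** Two per-sample masks: *upright* — the low-pass
   (< 0.5 Hz) vertical-axis component exceeds cos(45°)·g, i.e. the device
   is within 45° of vertical; *moving* — the 1 s sliding SD of the
   acceleration magnitude exceeds 0.1 m/s². Maximal runs of
   upright-AND-moving, with gaps ≤ 2 s merged and runs < 10 s dropped, are
   candidate bouts; each is confirmed by requiring that event detection
   finds at least 4 alternating initial contacts inside it. These
   thresholds are standard actigraphy heuristics; none is identified by
   the data alone, so all live in `gait_config()`.
3. **Vertical acceleration.** Within a bout the gravity-aligned axis is the
   one whose mean is closest in magnitude to 1 g (sign-corrected); gravity
   is removed by subtracting the bout mean. If no axis is within 30° of
   gravity the device was worn incorrectly and the bout errors out.
4. **Event detection.** The vertical acceleration is integrated (cumulative
   trapezoid, linearly detrended against integration drift) and then
   differentiated with a Gaussian continuous wavelet transform; initial
   contacts (IC, heel strike) are the minima of that signal, and a second
   application of the same transform yields the signal whose maxima are
   final contacts (FC, toe off). We use the correlation convention for the
   Gaussian-derivative wavelet — the output is the *negative* of the
   smoothed derivative — which is what places the heel-strike impulse at a
   minimum of the once-differentiated signal.
5. **Pairing and sides.** Each IC is matched to the first unused FC between
   0.1·T and 0.9·T later (T = median inter-IC interval); unmatched events
   are dropped and counted, and a bout with > 25% unmatched events is
   flagged low-quality. A lumbar sensor cannot observe which foot struck,
   so sides are assigned by strict alternation from a configurable first
   side; every asymmetry statistic is an absolute L/R difference and is
   therefore invariant to that choice (tested).
6. **Characteristics.** For the step starting at IC_i: step time
   IC_{i+1}−IC_i; stance time FC_i−IC_i; swing time IC_{i+2}−FC_i. Step
   length comes from the inverted-pendulum model: the vertical CoM
   excursion h over the step gives length 2·sqrt(2·l·h − h²) for pendulum
   (leg) length l. No correction factor is applied; l defaults to 0.9 m
   and must be set per participant for absolute accuracy. Step velocity is
   length/time, exactly, per row. Undefined components are `NA`, never
   zero, and excluded from summaries.
7. **Windows and domains.** Bouts are tiled into consecutive 30 s windows
   from the bout start (tails discarded). Per window and characteristic:
   mean, sample SD (n−1; a config flag switches to population), and
   asymmetry = |mean of L steps − mean of R steps|. The 13 window
   statistics map onto the four domains: pace (mean step velocity, mean
   step length), rhythm (mean step time, mean swing time), variability
   (all five SDs), asymmetry (step/stance/swing time and step length).
8. **Anomalies and review manifest.** A step value is anomalous on a
   characteristic when its absolute deviation from the recording-wide
   median exceeds k = 3 scaled MADs (1.4826·MAD). The rule is an explicit,
   deterministic concretisation of "flag the peaks a clinician would
   circle"; the medians are recording-wide so that atypical terrain stands
   out against the participant's habitual gait. Windows are ranked by
   anomaly count, then maximal score, then start time, and the top windows
   are written with human-readable reasons and (optionally offset)
   video-timeline timestamps.

## Numerical choices

Three discretisation details matter and are easy to get wrong:

* **Integration constant.** The "zero mean velocity per step" assumption is
  imposed with the *trapezoid* (integral) mean, not the arithmetic sample
  mean: a step interval sampled inclusively at both ends double-counts the
  endpoints at the 1/n level, and the resulting offset integrates into a
  spurious linear drift of several percent of the CoM excursion.
* **Boundary samples.** The velocity sample at a step boundary straddles
  the heel-strike impulse and does not represent pendular motion; both
  boundary samples are replaced by quadratic extrapolation of the adjacent
  interior samples before the second integration.
* **Coarse-to-fine event timing.** Contact minima are first located at the
  gait-scale wavelet (centre frequency matched to the dominant spectral
  peak of the integrated signal in 0.5–3 Hz, falling back to 2 Hz with a
  logged warning if no peak exists), then refined at a quarter of that
  scale within half the minimum event separation. Without refinement the
  broad wavelet biases each contact toward its neighbours, which visibly
  attenuates left/right step-time asymmetry (we measured ~0.08 recovered
  from a true 0.10 s asymmetry before refinement, ~0.098 after).

The wavelet scale policy, prominence threshold (0.2 × robust amplitude,
the 95th percentile of absolute deviation from the median), minimum event
separation (0.25 s) and edge trim (0.5 s) are all exposed in
`gait_config()` and recorded in every run record, because the scale is the
algorithm's main free parameter and reproducibility demands it be logged.

## The synthetic test bed

The study's raw recordings are not deposited, so validation rests on a
generator whose ground truth is exact. The vertical CoM trajectory is a
chain of inverted-pendulum circular arcs: within a step of chord s and
pendulum length l, height h(x) = sqrt(l² − (x − s/2)²) − sqrt(l² − (s/2)²)
traversed at constant horizontal speed. Vertical acceleration is obtained
by dense finite differencing of the *analytic* vertical velocity at
half-sample offsets. Two properties follow. First, the velocity jump at
each step transition (the heel-strike impulse) lands as a one-sample spike
exactly at the contact instant — the physically necessary upward impulse
that makes the walking-average of vertical acceleration zero, and the
waveform feature the CWT detector keys on. Second, cumulative trapezoid
integration telescopes through this construction, so the analysis pipeline
is an almost exact algebraic inverse of the generator: noise-free, the
reconstructed per-step CoM excursion matches the constructed arc height to
about 0.1% on average and the pendulum formula returns the constructed
chord exactly (2·sqrt(2lh − h²) with h = l − sqrt(l² − (s/2)²) simplifies
to s).

Defaults are the benchmark walking condition: 0.524 s mean step time with
0.045 s per-step SD, 0.562 m step length on both sides, 0.9 m pendulum,
0.3 m/s² white sensor noise (the device noise level is not characterised
in the source material; 0.3 m/s² is deliberately pessimistic for a modern
MEMS accelerometer), yielding ~4.5 cm CoM excursion — a typical adult
walking on level asphalt. Per-side means are configurable for asymmetric
gait; a 30 s walk at the default cadence contains 57 complete steps.
Multi-activity schedules concatenate standing, lying and walking; lying
rotates gravity onto a horizontal axis with a 1 s raised-cosine blend, so
posture transitions carry no synthetic discontinuity. Walks start and end
at zero vertical velocity through an ordinary contact impulse, so the gait
signal itself needs — and gets — no taper; `simulate_walk()` places the
walk between 3 s standing margins so bout extraction has real boundaries
to find. Ground-truth final contacts are defined as contralateral toe-off
(contact + 0.12 s double support). The generator emits no toe-off
waveform signature, so FC *timing* is validated structurally (one FC
paired between consecutive ICs, positive stance) rather than against
truth; every acceptance-grade claim rests on IC timing, which is validated
to ±0.05 s under noise.

What the generator does **not** emulate: arm swing and upper-body
artefacts, turning, slopes and stairs kinematics (stairs are emulated only
as elevated step-time variability), soft-tissue resonance, sensor drift
and temperature effects, and any gyroscope channel. Passing tests
demonstrate that the implementation inverts its own signal model and is
robust to white noise and timing jitter — not that it is clinically
accurate on real-world recordings; that requires instrumented-walkway or
force-plate ground truth.

## Worked example

```{r example}
params <- sim_params(duration_s = 65, seed = 7)
sim <- simulate_walk(params)
context <- context_track(
  start = c(0, sim$truth$walk_start, sim$truth$walk_end),
  end = c(sim$truth$walk_start, sim$truth$walk_end,
          recording_duration(sim$recording)),
  terrain = c("stand", "asphalt", "stand"),
  environment = c(NA, "outdoor", NA))
an <- analyze_gait(sim$recording, context = context)
an
glance(an)
head(tidy(an), 13)
```

```{r plots, fig.height = 6}
autoplot(an$steps)
```

## Problem sizes used in the test suite

Validation runs are sized for a desk machine: 30–65 s recordings at
100 Hz, 50-simulation sweeps for event-detection recovery (step times
0.45–0.65 s, noise up to 0.5 m/s²), and 20 seeds × 3 variability levels
for the summary-statistic recovery and monotonicity checks. These sizes
give standard errors comfortably below the tolerances being asserted
(e.g. SE of the asymmetry estimate ≈ 0.004 s against a ±0.02 s band).

## Known limitations

* The inverted-pendulum model is valid for straight, level walking; on
  stairs or turns its step-length output is systematically wrong, which is
  precisely why the context-stratified view exists.
* Leg length is a per-participant constant the model cannot infer;
  absolute step lengths scale with it.
* First-side assignment is arbitrary, so left and right are labels of
  convenience; only |L−R| quantities are meaningful.
* The bout thresholds are heuristics chosen for a lumbar sensor at 100 Hz;
  other wear locations need re-tuning.
* Clock synchronisation between sensor and any video timeline is assumed
  up to the constant offset in `gait_config(sync_offset_s=)`.
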