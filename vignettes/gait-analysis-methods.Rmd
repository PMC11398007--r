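---
title: "Methods: from 2D keypoints to gait metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from 2D keypoints to gait metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitway)
```

`gaitway` computes spatiotemporal gait metrics from 2D pose keypoints
recorded while a subject walks a virtual walkway of known length. This
vignette explains the model behind each stage, the parameters that
matter, what the synthetic walker does and does not emulate, and the
design decisions taken where the problem was genuinely open.

## 1. Data model

A recording is a stream of frames at nominally 60 fps; each frame holds
one keypoint per entry of a fixed 25-joint roster (head/trunk landmarks
plus left/right limb chains down to heel, big toe and small toe — see
`joint_names()`). Every keypoint is `(joint, x, y, quality, t)` with
pixel coordinates (origin top-left, y down) and a detector confidence in
[0, 1]. Missingness is always encoded as `quality = 0`, never as an
absent row, so every downstream matrix is dense and frame-aligned.

Real detectors drop joints for a few frames at a time. `fill_missing()`
linearly interpolates gaps up to `max_gap_frames` (default 3 frames,
50 ms at 60 fps) and tags the filled points. The default is deliberately
conservative: interpolating across longer gaps would fabricate kinematic
detail exactly where event timing is measured.

## 2. Coordinate systems

Three views of the same motion:

* **Screen view** — raw pixels, device-dependent.
* **Camera view** — `x' = (x - cx)/fx`, `y' = (y - cy)/fy`. An affine,
  exactly invertible normalization that removes the device's focal
  length and principal point.
* **World view** — per-frame depth `z` (from the AR session) and a
  reference depth `z0` lift the normalized coordinates to 3D, in
  unitless multiples of `z0`.

Two world-view conventions are implemented. The default, `pinhole`,
back-projects: `X = x'·(z/z0)`, so a lateral displacement of fixed
metric size maps to the same `X` difference at every depth — the
self-consistent choice for measuring lengths. The alternative,
`as_printed`, uses the reciprocal factor `z0/z`, which *shrinks* lateral
coordinates with distance; it is retained because depth-normalized
formulations of this form appear in the field, and the two coincide
exactly at `z = z0` (they differ by `(z0/z)²` otherwise, a relation the
test suite asserts). Which convention a production system uses is not
generally recoverable from published formulas alone; making both
selectable keeps results comparable either way.

Metric scale is anchored by the walkway, not the camera: the AR start
and end markers are a known distance apart (4.0 m by default — the
standard clinical distance that excludes initial acceleration; 10 cm
waypoints subdivide it), fixing meters-per-world-unit in
`walkway_definition()`. Progression is the scalar projection of a
reference joint (the pelvis, `mid_hip`) onto the start→end axis;
the lateral axis is its in-ground-plane orthogonal.

## 3. Distance-adaptive smoothing

Keypoint noise in *normalized* coordinates grows with the subject's
distance: pixel amplitudes shrink while detector noise stays roughly
constant in pixels. The smoother is therefore a Savitzky–Golay filter
whose window widens with depth: at frame *i* the window is the nearest
odd value of `base_window · (z_i/z0)` clamped to
`[min_window, max_window]` (defaults 9, 5, 21 frames — 150 ms at the
reference depth), with polynomial degree 3, the standard choice for
kinematic traces (it preserves local extrema far better than a moving
average). The mapping from distance to window width is linear by
default and replaceable via `smoothing_policy()`; no canonical form
exists, so the policy keeps it explicit and auditable (the realized
per-frame windows are attached to every smoothed track).

Numerical choices: weights come from the exact least-squares projection
(`savgol_coefficients()`, which reproduces polynomials up to the fitting
degree to 1e-9 and always sums to 1); boundaries are handled by
symmetric window *shrinkage* rather than padding, so no data is invented
at walk onset/offset where reaction and ignition times are measured;
samples flagged missing are excluded from the local fits rather than
zero-filled.

## 4. Gait events

Only one detection rule is canonical in this setting: toe off occurs at
the troughs of a foot keypoint's cyclic signal, with troughs defined as
the "consistent lowest local mean". `detect_troughs()` operationalizes
that phrase as: local minima of a centered moving average (window 5
frames) that reach a prominence of at least 20% of the signal's
peak-to-peak range, de-duplicated so that no two troughs are closer than
`min_separation` (0.4 s, about half a gait cycle at fast cadence; the
deeper trough wins, ties go to the earlier frame). The phrase has no
unique formalization, so every ingredient is exposed in
`trough_policy()`.

The remaining events use standard kinematic constructions:

* **Heel strike** — maxima of heel progression relative to the pelvis
  (the forward-position-extremum rule familiar from marker-based gait
  analysis), reusing the trough machinery on the negated signal.
* **Heel rise** — first sustained rise of heel height above its
  early-stance baseline within each stance interval, with a sub-frame
  correction that subtracts the lead introduced by the detection
  threshold (threshold / local slope), so the reported frame tracks the
  true lift-off rather than the threshold crossing.
* **Feet adjacent** — minima of the inter-ankle progression distance,
  attributed to the swinging side.
* **Tibia vertical** — the knee passing directly above the ankle along
  the progression axis, detected as a hysteresis zero crossing of the
  knee-ankle progression difference (hysteresis 10% of the signal's
  range, so noise near zero cannot fire repeatedly).

Two plausibility guards keep the detector quiet when there is no gait:
signals whose total excursion stays below small physical floors (1 cm
vertical, 5 cm progression) are not searched, and all events are gated
to the interval in which the pelvis progresses faster than 0.05 m/s
sustained for 0.3 s (dilated by 0.25 s). A subject standing still —
even with realistic keypoint noise — produces no events.

Stance runs from heel strike to the next ipsilateral toe off, swing from
toe off to the next heel strike; incomplete boundary phases are dropped
and out-of-order event pairs raise a sequencing warning rather than
corrupting the tiling.

## 5. Metrics

Gait speed is walkway length divided by the time between the pelvis's
interpolated start- and end-line crossings — the same definition an
instrumented walkway uses. Stride length is the progression distance
between consecutive ipsilateral heel strikes; the heel's position at a
strike is estimated as the mean heel progression over the interior of
the stance plateau (the heel is stationary while planted), which
suppresses per-frame keypoint noise far better than reading a single
frame. Step length uses consecutive contralateral strikes; cadence is
steps inside the walkway per minute of walk time; base of support is the
mean inter-ankle lateral distance during double support.

Reaction and ignition times have no standard operational definition in
this context, so the package states one: movement onset is the first
time pelvis progression velocity exceeds 0.05 m/s sustained for 0.2 s;
reaction time is onset minus the command time, ignition time is the
start-line crossing minus onset. Both thresholds are plain arguments.

Failed preconditions (a walk that never reaches the end line, fewer than
two usable heel strikes) yield partial metrics with explicit `NA` fields
and a human-readable note — never silent zeros.

Joint angles use the planar included-angle formula at a vertex
(`joint_angle()`), with the cosine clamped to [−1, 1] so the function is
total; degenerate triples (vertex coincident with an endpoint within
1e-9) are an error for scalar calls and a masked frame in traces. The
default triples are knee = (hip, knee, ankle), hip = (shoulder, hip,
knee), ankle = (knee, ankle, big toe), per side; the raw included angle
is reported (flexion is 180° minus it). By default traces are computed
on the depth-corrected world view, where the side-view geometry is
undistorted.

## 6. The synthetic walker

`simulate_walk()` is not a fixture but a first-class model, because
every accuracy claim in the package is measured against it.

The walker is planar-sagittal with parameterized lateral geometry. The
pelvis advances at constant speed; each foot alternates ground-anchored
stance (zero progression velocity — the invariant that makes heel-strike
placement well-defined) with constant-velocity swing covering one stride.
Heel-strike placements are positioned so the foot lands ahead of the
pelvis by half a stance phase's progression, giving a symmetric
fore-aft excursion. Foot verticals are smooth periodic profiles chosen
so each event has an unambiguous analytic time: toe height is a raised
cosine with its unique minimum exactly at toe off; heel height is zero
until the heel-rise phase (40% of the cycle) and a half-sine until the
next strike. Knees follow two-link inverse kinematics between hip and
ankle with segment lengths 0.245·height and pelvis height 0.516·height —
proportions chosen so the knee is near extension at mid-stance and
flexes ~45° in swing, and so the tibia-vertical event exists at every
supported speed. Trunk, head and arms ride on the pelvis with
phase-locked arm swing. Speed, cadence and stride length always satisfy
`speed = stride · cadence / 120`; when only speed is given, cadence
follows the affine rule `75 + 35·speed` (≈ 96–124 steps/min across
0.6–1.4 m/s, a realistic co-variation).

The scene is viewed side-on by a pinhole camera 4 m from the walkway
midline (fx = fy = 700 px, 1080p geometry), which exercises every
coordinate transform while keeping all quantities analytically
recoverable. Gaussian pixel noise, per-keypoint quality scores
(N(0.9, 0.05) clamped) and independent dropout are applied after
projection, under a single seed; the simulator saves and restores the
global RNG state. Ground truth — event times, crossing times, speed,
stride/step lengths, step count, knee-angle traces — is emitted from
the continuous model (closed forms where available, root-finding on the
model functions for tibia-vertical and feet-adjacent during the
asymmetric initiation cycles), never by re-detecting from the generated
data.

What the simulator does *not* emulate: acceleration and deceleration
transients (gait starts at steady speed — the standing-to-walking
transition is stylized, which is why event-timing accuracy is evaluated
inside the walkway interval, the region the walkway exists to
standardize), pathological or asymmetric gait, pelvis vertical
oscillation, camera motion or rolling shutter, lens distortion,
structured (non-Gaussian, joint-correlated) detector error, and depth
noise (AR depth is taken as exact). Passing tests therefore demonstrate
correctness of the pipeline's geometry, signal processing and event
logic under realistic noise magnitudes — not robustness to every failure
mode of real pose detectors.

## 7. Accuracy under the reference conditions

The package's accuracy summary (`scripts/acceptance.R`, mirrored by a
test) simulates 50 walks with speeds uniform in 0.6–1.4 m/s, 2 px
keypoint noise and 1% dropout over the 4 m walkway, runs the full
pipeline with defaults, and reports the maximum relative error of gait
speed and mean stride length against ground truth. Problem sizes —
50 walks of roughly 400–700 frames — were chosen so the whole analysis
runs in seconds on a single core while still giving the max statistic
about 300 stride measurements to range over.

```{r cohort, eval = FALSE}
cohort <- simulate_cohort(50, c(0.6, 1.4), noise_sd = 2,
                          dropout_prob = 0.01, seed = 42)
run_validate(cohort)$stats
```

Noise-free walks recover speed and stride to within discretization
error, and all five event types land within one frame of their analytic
times inside the walkway interval; the noisy cohort stays within a few
tenths of a percent on speed and stride (the tests assert a 2% bound).

## 8. Known limitations

* Angles are planar; true 3D (anatomical) joint angles are out of scope.
* The as-printed world convention distorts lengths off the reference
  depth by design; measurements should use the pinhole convention.
* Event rules other than toe off are this package's operational choices;
  other systems' definitions (e.g. force-plate heel strike) will differ
  by a systematic, typically sub-cycle offset.
* The walkway must be crossed completely for speed to be defined; there
  is no partial-walkway extrapolation.
* Depth is trusted as given. Noisy depth propagates linearly into world
  coordinates and is not modeled.
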