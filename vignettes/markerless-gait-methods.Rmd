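---
title: "Methods: markerless 3D gait analysis with gaitless"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: markerless 3D gait analysis with gaitless}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and numerical choices
behind `gaitless`, in the spirit of a methods section: every tunable that
matters, its default, and why; what the bundled simulator does and does not
emulate; and the limitations a user should know before trusting a number.

## The pipeline and its assumptions

The package covers a markerless gait pipeline *downstream* of a neural 2D
pose detector: per-view 2D keypoints with confidences plus calibrated,
synchronized cameras go in; 3D trajectories, gait events, spatio-temporal
parameters, joint-angle curves and system-comparison statistics come out.
The analysis-only entry point accepts already-triangulated 3D trajectories
(e.g. exported from a marker-based system), so both arms of a
marker-vs-markerless comparison flow through identical code.

Standing assumptions: cameras are calibrated and frame-synchronized
(no rolling-shutter or sync correction); the subject walks roughly in a
straight line on level ground (needed for the progression/lateral
decomposition of lengths and widths); world units are meters internally,
with declared `mm` inputs converted on read; time is `frame / fps` with
0-based frames.

## Cameras and triangulation

A camera is a pinhole model `x = K · distort([R|t] X / depth)` with
Brown–Conrady distortion (radial `k1`, `k2`, tangential `p1`, `p2`) —
the model produced by standard checkerboard calibration. Observations are
undistorted (fixed-point inversion, 20 iterations, exact to well below
1e-9 in normalized units for lens-like coefficients) *before* the linear
solve, so triangulation itself is distortion-free.

Per sample, triangulation solves the DLT system — two rows
`x·P3 − P1`, `y·P3 − P2` per view on normalized coordinates, smallest
right singular vector — then polishes with a damped Gauss–Newton
minimization of the confidence-weighted squared reprojection error.
Refinement is on by default: under noise it is never worse than the linear
solve (the acceptance suite checks `refined RMS ≤ DLT RMS` in ≥95% of
noisy trials), and at zero noise both agree to machine precision.

Degeneracy: a sample is flagged unreliable (not dropped) when the maximum
pairwise ray angle is below 1° or when the ratio of the first to the
*third* singular value of the DLT matrix exceeds 1e8. The fourth singular
value is ~0 for any consistent observation set, so it carries no geometric
information; σ1/σ3 is what blows up when rays are parallel. These
thresholds are conservative defaults; the flags surface as the
`"unreliable"` attribute of `triangulate_series()` output.

Confidence weighting of the solve is on by default but configurable —
whether the original system weighted by detector confidence is not
documented, and the package treats it as a user choice. Down-weighting a
corrupted view never increases the median 3D error in the test suite.

## Temporal filtering

`butterworth_lowpass()` designs the digital Butterworth filter by bilinear
transform of the analog prototype (poles on the Butterworth circle at the
prewarped cutoff, all zeros at z = −1, numerator scaled for exactly unit
DC gain) and applies it forward–backward (zero phase) with odd-reflection
padding and steady-state initial conditions. Zero-phase application is the
biomechanics norm: it introduces no group delay, so event timing is
preserved (a filtered symmetric pulse keeps its argmax). `order = 4` means
the *designed* filter is 4th order before the two passes — so the
two-pass magnitude is the squared response and the cutoff remains the
half-power point (amplitude 0.5 at the cutoff frequency, which the
acceptance suite verifies to ±0.02). Users who want the combined pass to
be 4th order can set `order_convention = "effective"`.

The pipeline uses 3 Hz for event detection and 12 Hz for kinematics —
both 4th order. The 3 Hz filter exists only to make the speed thresholding
robust; all measurements are taken from the 12 Hz-filtered signals.

Gap handling: interior gaps up to `max_gap_frames` (default 10, i.e.
0.33 s at 30 fps) are filled by a natural cubic spline through the valid
samples; longer gaps stay missing and are listed in a report; edge gaps
are held constant rather than extrapolated. Differentiation is central
differences (one-sided at edges), second-order accurate.

## Gait events

A gait cycle runs from one heel strike to the next of the same foot;
stance ends at toe-off. Detection is speed-based, in two stages.

**Coarse stage** (the classical detector): filter the heel trajectory at
3 Hz, take the Euclidean norm of its 3D velocity, and find low-speed
intervals by hysteresis thresholding — enter below 15% of the record's
95th-percentile speed, leave above 1.25× that. Intervals shorter than
0.1 s are discarded, and an interval already low at the record start is
not an event (a strike must be *entered* from swing). The adaptive
threshold makes the detector invariant to walking speed; the published
description ("speed close to zero") fixes no constant, so these values
are package choices: 15% sits well above realistic measurement-noise
floors and well below swing speeds (which peak at several m/s), 0.1 s
rejects chattering without excluding even very short stances, and the
1.25× hysteresis suppresses threshold flicker.

**Refinement stage.** The 3 Hz filter that makes thresholding robust also
smears the speed profile by several frames, so the raw threshold crossing
is biased into the swing by 1–2 frames — too coarse for per-cycle stance
percentages at 30 fps, where one frame is ~3% of a cycle. Events are
therefore re-localized on the *unfiltered* trajectory: within each
candidate interval the exact rest run is found (central-difference speed
at the noise floor, estimated from the interval's lower speed quartile,
with single-frame spikes closed), and the contact/lift instant is
extrapolated to sub-frame precision from the displacements just outside
the run. The extrapolation inverts a minimum-jerk swing model — the
standard smoothness model for human limb trajectories — whose stride
length and swing duration are estimated from the record itself (rest-run
plateau spacing; swing duration re-estimated once from the first-pass
toe-offs, since rest-run edges are noise-dependent). Displacements are
projected on the progression axis, excluding vertical clearance. Where no
stride model is available the fallback is per-component power-law
extrapolation (cubic along progression, quadratic vertically). Finally,
because steady-gait strikes lie on a near-periodic lattice and stance
durations are stable across cycles, sub-frame estimates within one frame
of the record's best-fit lattice (strikes) or median stance offset
(toe-offs) are pooled before rounding; estimates deviating by more than a
frame — genuinely irregular cycles — are kept as-is.

This design recovers simulator events *exactly* (zero error at zero
noise across stride times 0.9–1.3 s and duty factors 0.55–0.65) and
stays within ±2 frames at 3 mm trajectory noise. The pooling step assumes
reasonably steady walking within a record; for strongly irregular or
pathological gait, pass `refine = FALSE` to fall back to the plain
threshold detector (at the cost of the 1–2-frame filter bias), or inspect
per-cycle deviations — the pooling never moves an estimate by more than
one frame.

Degenerate inputs (stationary subject, running with no low-speed
interval) yield an empty event list with a diagnostic attribute, never an
error.

## Spatio-temporal parameters

Six per-cycle parameters, measured on 12 Hz-filtered trajectories:

* *Stride length*: horizontal displacement of the ipsilateral heel between
  consecutive strikes. Vertical displacement is excluded (level-ground
  assumption).
* *Stride time*: cycle duration in seconds.
* *Stance / swing phase*: the cycle's event fractions ×100; they sum to
  100 exactly by construction.
* *Step (stride) width*: mean absolute lateral separation of the two heels
  across the cycle's frames, where "lateral" is perpendicular to the
  progression axis (first principal axis of horizontal pelvis
  displacement, signed along net motion). The phrase "distance between the
  feet across the cycle" is read as a cycle average.
* *Speed*: mean speed of the pelvis-root keypoint over the cycle, a proxy
  for the center of mass. A model-based COM would need a musculoskeletal
  model; the proxy is documented and configurable by supplying a different
  root binding in the skeleton. Speed ≈ stride_length/stride_time on
  straight walks but is not identical to it (the pelvis oscillates).

All six are invariant to rotations about the vertical axis plus
translations (verified to 1e-7 relative); lengths scale linearly and times
not at all under uniform scaling.

## Joint angles

The published pipeline estimated joint angles by scaling a full-body
musculoskeletal model and running inverse kinematics in external software.
This package deliberately replaces that step with direct geometric angles:
sagittal/frontal gait angles are well-defined from segment vectors, the
external-tool dependency disappears, and the TRC exporter keeps the
model-based route open for users who want it. The cost is a
convention-dependent offset relative to musculoskeletal-model angles —
documented, not hidden: curves from this package and from an IK pipeline
agree in shape but may differ by roughly constant offsets per angle.

Definitions (per frame, then time-normalized to 101 nodes):

* Pelvis frame: lateral axis along right-hip→left-hip; up axis along
  pelvis-root→trunk when the skeleton binds a `trunk` role (without a
  trunk reference, pelvic tilt is unobservable from two hip points and
  world-vertical is used); forward = up × lateral, signed along
  progression; orthonormalized with up as the primary axis.
* Hip flexion: signed angle of the thigh against the pelvis down axis in
  the pelvis sagittal plane, thigh-forward positive.
* Knee flexion: 180° minus the angle at the knee between thigh and shank;
  extension 0, flexion positive.
* Ankle dorsiflexion: signed sagittal angle between foot (heel→toe) and
  shank (knee→ankle), minus the same angle at the cycle's mid-stance
  frame (strike + half the stance, rounded to the frame grid) — so
  dorsiflexion ≈ 0 at foot-flat. The raw foot–shank angle is ~90° at
  neutral, so *some* offset convention is unavoidable;
  `ankle_reference = "absolute"` disables the subtraction.
* Hip abduction: signed thigh angle in the pelvis frontal plane,
  away-from-midline positive (side-aware sign).
* Pelvis tilt: angle of the pelvis forward axis below the horizontal,
  anterior tilt positive.

Signs follow gait-analysis convention throughout (flexion, dorsiflexion,
abduction, anterior tilt positive). Curves are invariant to rigid motions
(1e-6°), near-cyclic on steady gait, and mirror-symmetric under left-right
reflection; the simulator's prescribed profiles are recovered within 2°
RMS at zero noise.

## Pose-estimation metrics

PCKh@τ counts an estimate as correct when its 2D distance to ground truth
is **strictly** below τ times the head-segment length; ties count as
incorrect. The head segment defaults to the record-mean distance between
the skeleton's `head_top` and `head_base` keypoints (`head` and `nose` in
the bundled 21-keypoint skeleton) — the endpoints of the "head bone link"
are not standardized, so the binding is explicit and overridable, and a
per-frame reference is accepted. Because pooling conventions differ across
the literature, the pooled-over-samples percentage and the mean of
per-keypoint percentages are both reported. MPJPE is the mean 3D Euclidean
distance over valid (frame, keypoint) pairs, conventionally reported in
millimeters. Missing samples are excluded pairwise from numerator and
denominator of both metrics.

## Statistical comparison of two systems

Scalar parameters are compared with two-sided paired t-tests
(df = n − 1), *without* multiplicity correction: for an agreement study
this is the conservative direction, since corrections would make
differences harder to find. Zero-variance differences make p undefined;
the result is flagged degenerate with t = 0 (zero mean difference) or
±Inf.

Angle curves are compared with a one-dimensional SPM paired t-test at
α = 0.05, two-sided. The pointwise t statistic is computed at each of the
101 nodes; the family-wise critical threshold `t*` solves the
expected-Euler-characteristic equation for a 1D t field,
`α/2 = P(t_ν > u) + resels · ρ1(u)` with
`ρ1(u) = √(4 ln 2)/(2π) · (1 + u²/ν)^(−(ν−1)/2)` and
`resels = (nodes − 1)/FWHM`. The field smoothness (FWHM) is estimated
from the gradient variance of the normalized residual curves (the
standard 1D estimator). `t*` is clamped between the scalar-t and the
Bonferroni-over-nodes critical values — its exact limits for infinitely
smooth and white fields — which also guards the approximation at very
rough smoothness estimates. Cluster-level p-values use the expected
cluster count and an exponential cluster-extent approximation; they are
approximate and so labelled.

Because random-field-theory validity at n = 16 with non-Gaussian
residuals is not guaranteed, a distribution-free permutation route is
included: `t*` as the (1 − α) quantile of the max-|t| distribution over
sign flips of the paired differences, exhaustive when `2^n ≤ 10000`,
otherwise seeded Monte Carlo (the seed is required there — determinism is
a package-wide contract). On smooth null fields both routes hold the
family-wise error within [0.03, 0.07] of the nominal 0.05 over 2000
replicates, agree within 10% on `t*`, and detect a 3-residual-SD offset
injected over 70–80% of the cycle in ≥95% of replicates — the acceptance
suite re-verifies all three. Exact numerical parity with any specific SPM
implementation is *not* claimed; the estimator and cluster-p formulas are
stated above so results are reproducible from this package alone.

## The synthetic walker

The simulator is kinematic, not dynamic: its purpose is exact ground
truth, not biomechanical fidelity. The pelvis advances at constant mean
speed with small sinusoidal vertical (±1.5 cm) and lateral (±2 cm)
oscillation and a gently oscillating anterior pelvic tilt (4° ± 1.5°);
each heel is anchored — exactly zero velocity — during stance and
advances by one stride length during swing along a minimum-jerk
horizontal path with a sin² vertical clearance bump (12 cm); the foot
pitches smoothly (C¹) in swing; the knee is solved by exact two-link
inverse kinematics; left and right are antiphase. The stride period is
quantized to whole frames so events fall exactly on the frame grid, which
is what makes closed-form recovery tests possible: stance percentage is
`100 · duty_factor` exactly, stride metrics are exact functions of the
configuration, and noise/missingness are applied only *after* ground
truth is recorded, through one seeded generator.

Defaults are set to normal adult gait magnitudes (stride 1.35 m, stride
time 1.13 s, stance 59.2%, step width 0.10 m, 30 fps, three ~1.3 MP
cameras at 3.5–4.5 m viewing a 6 m walkway) so that recovered parameter
tables look like real summary tables. The first strike occurs 0.5 s into
the record, as real recordings have lead-in before the first clean event.

What the simulator does **not** emulate: soft-tissue artifact, cadence
and stride-length variability, turning, double-support asymmetries,
detector-specific error structure (blur-dependent, often heavy-tailed and
view-correlated — the renderer's pixel noise is isotropic Gaussian),
occlusion patterns (missingness is i.i.d.), or realistic joint ranges
(the constant-pelvis-height constraint forces a deeply flexed knee
throughout stance). A green end-to-end test therefore establishes that
the *algorithms* are implemented correctly and meet their stated
tolerances under the stated noise — it does not certify accuracy on real
video, which depends on detector quality the package does not model.

## Numerical choices

* All randomness flows through explicit seeds; simulator and renderer
  restore the caller's RNG state.
* Writers emit full double precision (17 significant digits), so
  write→read round-trips are bit-exact; the TRC writer uses 8 decimals
  (sub-micrometer in meters).
* Undistortion: 20 fixed-point iterations; Gauss–Newton: ≤10 iterations,
  Levenberg damping, relative tolerance 1e-16.
* Ties/rounding: events are rounded to the nearest frame (half away from
  even follows R's `round`); the sub-frame estimators are unbiased at the
  frame grid, so the rounding convention only matters at exact half-frame
  boundaries, where either neighbor is within quantization error.
* Degenerate inputs error early with named fields (config validation
  happens before any computation; exit code 2 vs 3 separates config from
  data errors in the CLI).

## Known limitations

* Angle conventions differ from musculoskeletal-model output by
  per-angle offsets; compare shapes, or re-run the TRC export through an
  IK pipeline for model-based angles.
* The event refinement's steady-gait pooling assumes stable cadence
  within a record (see above for the irregular-gait escape hatch).
* Cluster-level p-values are approximations; node-level inference via
  `t*` is the calibrated quantity.
* The analysis-path statistics pair cycles by index when comparing two
  systems of the same trials; a proper multi-subject study should pair by
  subject and feed `compare_systems()` directly.
* PCKh/MPJPE evaluate whatever estimates they are given; the package
  contains no pose detector, so end-to-end accuracy claims about any
  specific network are out of scope.
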