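---
title: "Validating markerless joint-angle estimation: models, signal conditioning, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating markerless joint-angle estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinovalid)
```

## The problem

Marker-based optical motion capture is the accuracy reference for joint
kinematics, but its cost keeps it out of routine rehabilitation practice.
Consumer RGB-D cameras (Kinect V2, Orbbec Astra, Intel RealSense) and
monocular pose estimators (MediaPipe/BlazePose) deliver tracked 3D body
landmarks cheaply; the clinical question is whether joint angles derived
from those landmarks agree with the optical reference well enough to
substitute for a goniometer. `kinovalid` implements the full comparison
pipeline — landmark geometry, joint-angle computation, dual-rate signal
conditioning and synchronization, and agreement statistics — together with
a synthetic motion generator, so every stage is testable end to end without
recorded subjects.

## Geometry: from pixels to joints

Trackers that run on a colour image return landmarks in pixel coordinates.
With a registered depth frame and a pinhole model with focal length $f$ and
principal point $(x_o, y_o)$, a landmark at pixel $(x_p, y_p)$ observed at
depth $z$ lifts to sensor-frame coordinates

$$ (x_w, y_w, z_w) \;=\; \Bigl( \frac{(x_p - x_o)\,z}{f},\;
   \frac{(y_p - y_o)\,z}{f},\; z \Bigr). $$

`backproject()` implements this relation and `project_points()` its exact
inverse; the pair round-trips to floating-point precision, which the test
suite checks over $10^5$ random image points. Depth is sampled at the
nearest integer pixel (`overlay_depth()`); when that pixel holds no valid
depth the median of the valid 3×3 neighbours substitutes, and a landmark
with no usable depth is *flagged*, never silently dropped — downstream loss
accounting needs to see it. Pixel coordinates use the image convention
(origin top-left, y down); the single flip to anatomical "up" happens in
the body-basis construction, not in the geometry.

Lens distortion and RGB-to-depth registration are out of scope: frames are
assumed registered, as sensor SDKs deliver them.

## Body coordinates and in-plane angles

Angles are defined in a body-anchored coordinate system in the ISB spirit.
From trunk landmarks, `build_body_basis()` takes the longitudinal axis
$\hat y$ along mid-spine → spine-top, the mediolateral axis $\hat x$ as the
left-hip → right-hip direction orthogonalized against $\hat y$, and
$\hat z = \hat x \times \hat y$. The published description of the
$\hat z$ construction is internally garbled; the Gram–Schmidt form used
here is the unique right-handed orthonormal completion consistent with the
stated change-of-basis matrix, and is validated by a rotation-invariance
property: rigidly rotating every landmark rotates the basis identically
and leaves body-frame coordinates unchanged to $10^{-9}$.

A sensor-frame vector $v_{sc}$ converts to body coordinates as
$v_{bc} = B^{-1} v_{sc}$, where the columns of $B$ are the basis vectors;
for an orthonormal $B$ this is just the transpose, but the explicit,
guarded inverse is used so the contract survives a numerically degraded
basis.

`angle_in_plane()` computes the moving vector (distal − proximal joint) in
body coordinates, requires it to lie in the requested anatomical plane —
its angle to the plane normal within `tolerance` of 90° — and returns its
angle to the plane's in-plane reference axis, in $[0°, 180°]$. Reference
axes are $-\hat y$ for the frontal and sagittal planes (anatomical neutral
"limb hanging down" reads 0°, full elevation 180°) and $\hat x$ for the
horizontal plane; only the frontal/longitudinal-axis pairing is dictated by
the source convention, the other two are the natural completion. The
default tolerance is 90°, i.e. disabled: no published tolerance value
exists, and a strict default would reject noisy real frames unpredictably.
Frames that fail become masked samples (gaps) carried forward explicitly;
the same trunk construction serves upper- and lower-limb requests, with
only the basis origin differing.

## The synthetic study

Because no recordings are deposited with the study this package grew from,
the generator *is* the data source, and its defaults are the study
conditions:

* **Trajectory.** Each recording is 5 repetitions of a raised-cosine
  excursion, $\theta(t) = \theta_0 + \tfrac{A}{2}(1 - \cos 2\pi f t)$, at
  $f = 0.5$ Hz (movements were executed at no more than 1 Hz). The raised
  cosine starts and ends at baseline with one maximum per repetition —
  exactly the structure the three-segment peak split assumes. Default
  amplitude is $A = 60°$, a mid-range executed amplitude across the six
  movement types modelled (hip abduction is typically executed near 40°,
  knee and elbow flexion near or beyond 90°); baseline is 10° so noise
  cannot fold the angle across 0°.
* **Rates.** Reference stream at 180 Hz, sensor streams at 30 Hz, the
  actual dual-rate setting being validated.
* **Noise.** Isotropic Gaussian position noise on every 3D landmark,
  default SD 5 mm — the sensors' noise was never characterized, so this is
  a single calibratable knob, not a claim about any device.
* **Start offsets.** Uniform in [0, 1] s per stream, so synchronization is
  never trivially the identity.
* **Dropouts.** Each recording is lost outright with probability 0.15,
  matching the mid-teens loss rate such multi-sensor recordings show in
  practice, to exercise the availability-grid accounting.
* **Camera.** Subject at 2.5 m (no published distance; a typical full-body
  working distance for consumer depth cameras), rotated 0° or 30° about
  the vertical axis according to the movement code's orientation token.
  Intrinsics default to a 512×424, f = 365 px depth camera.

`forward_kinematics()` inverts the angle computation exactly (the round
trip is tested to $10^{-6}$°), and `render_sensor_stream()` produces both a
noisy 3D stream and the 2D-landmark + depth pair, so the back-projection
path is exercised by the same recordings. In the orchestrated run, two of
the four simulated sensors take the depth-overlay path and two deliver 3D
joints directly — the same split the real sensor fleet had.

What the generator does **not** emulate: soft-tissue artifact, body-shape
variation, tracker-specific biases (MediaPipe's relative depth, Kinect's
skeleton model), occlusion-induced landmark jumps, and asynchrony between
colour and depth streams. Passing tests therefore demonstrate correctness
of the *pipeline*, not field accuracy of any sensor; the published
per-movement reference tables bundled with the package are the bridge to
real-world numbers.

## Signal conditioning and synchronization

Angle series are conditioned with a 7th-order Butterworth low-pass (cutoff
5 Hz for 30 Hz streams, 30 Hz for the 180 Hz stream) followed by a
7-sample moving average. Numerical choices worth stating:

* The Butterworth stage is applied forward–backward (zero phase). The
  source procedure does not say; peak-based synchronization requires the
  filter not to move peaks, which a causal 7th-order filter would do by
  tens of milliseconds. The effective attenuation order doubles.
* Forward–backward filtering is computed on a mean-removed, odd-reflection
  padded copy so the filter's zero initial conditions cannot inject edge
  transients; a constant series passes through bit-exactly, which is also
  the regression test for this choice.
* The moving average uses edge-reflection padding to preserve length.
* Gaps of at most 5 consecutive masked samples are filled linearly before
  filtering; anything longer marks the recording lost. Filling across a
  long gap would manufacture signal where the tracker saw nothing.
* The 30 Hz cutoff on the 180 Hz reference stream passes most of that
  band. It is retained as published — a faithful-but-odd choice, and with
  movements at ≤ 1 Hz an inconsequential one.

Repetition peaks are local maxima with prominence at least 20 % of the
signal range and spacing at least half a repetition period (estimated from
the dominant spectral component); no published detection parameters exist,
and these two rules are the weakest ones that reject filter ripple and
noise spikes on the synthetic conditions. The series then splits into
start → first peak, first → last peak, last peak → end, and each sensor
section is resampled onto the reference section's length with *local
quadratic (second-order) polynomial interpolation* — read as piecewise
quadratic, since a single global quadratic cannot represent a five-peak
signal. Quadratic interpolation is exact on quadratics (tested to
$10^{-9}$) and is the identity at equal lengths. Sections with fewer than
three samples fall back to linear interpolation with a warning. A
peak-count mismatch between a sensor and the reference is a
synchronization failure and loses the recording; alignment is by peaks
only, deliberately — not cross-correlation, not start-of-recording.

With zero noise and equal offsets, the aligned 30 Hz stream differs from
its own 180 Hz reference by ≈ 0.37° median. That residual is almost
entirely the 7-sample moving average: at 30 Hz its gain at 0.5 Hz is
0.9782 versus 0.9994 at 180 Hz, a ≈ 0.65 % amplitude mismatch, i.e.
≈ 0.4° of a 60° excursion at mid-slope. This is the irreducible floor of
the fixed conditioning chain, not an alignment error.

## Agreement statistics

Per aligned sample, the absolute error is $E_A = |\theta_s - \theta_Q|$;
its dispersion summary is $\mathrm{RMS} = \sqrt{\tfrac{1}{n}\sum x_i^2}$,
which bounds the mean error from above (a property test). Because such
error distributions are skewed (a Shapiro–Wilk pre-check records this),
medians summarize location, and comparisons across sensors use Friedman's
rank-sum test with paired Wilcoxon post hocs, blocked on movement
executions (the execution is the natural paired observation unit; the
study counts 505 of them). Significance is reported as `*` (p < 0.05) and
`**` (p < 0.001). Fully tied blocks leave Friedman's statistic undefined;
the package reports statistic 0, p = 1 — no rank information is no
evidence of difference.

A median error $m$ with SD $s$ is classified against the clinical
reference CR = 12.78° (published human goniometry error, SD 7.44°):
*excellent* if $m + s < \mathrm{CR}$, *good* if $m < \mathrm{CR}$,
*moderate* if $m \le \mathrm{CR} + 5°$, else *poor*. The moderate band is
judged on the median alone: that reading is the one that reproduces the
published verbal labels from the published summary values (a sensor at
11.60 ± 3.71 is *good* even though $m + s$ crosses CR). Pearson
correlations — computed on the synchronized angle series, not on errors —
band as poor < 0.5 ≤ moderate < 0.75 ≤ good < 0.9 ≤ excellent.

Table-level aggregation follows the published convention:
per movement, the median absolute error (pooled over recordings) and RMS;
per limb group, the arithmetic mean ± *sample* (n−1) SD of the six
per-movement values; the all-data row pools all twelve. Sample SD is the
variant that reproduces the published SDs from the published cells;
population SD does not. Recomputing the published group rows from the
bundled per-movement cells reproduces, at printed precision (±0.011,
the rounding noise of two-decimal cells), every row that is internally
consistent in the source; the Astra and Intel upper-limb median rows (and
hence their pooled all-data rows) are not derivable from their own printed
cells and are treated as typesetting errors, as is the lower-limb RMS
table, whose body duplicates the median table.

## Orchestration and loss accounting

`run_pipeline()` executes the whole study: for each volunteer × movement ×
recording index, it generates the reference and sensor streams, renders
them, computes, conditions and synchronizes the angle series, and collects
agreement statistics. Every failure mode — dropout, unfillable gap, failed
synchronization — marks that recording `x` in an availability grid instead
of aborting the run; `loss_accounting()` then reports lost/analyzed
counts, the loss percentage and the number of analyzed executions, with
`lost + analyzed = total` invariant. Movement codes
(`joint-movement-orientation-index`, e.g. `K-FLEX-FR-1`) parse through a
dialect-tolerant grammar because the source materials themselves mix
English and Portuguese initials (`Q-` hip, `J-` knee, `C-` elbow, `O-`
shoulder, `INL`, `ADB`).

The orchestrated run is deterministic under its seed: identical seeds give
identical reports, which is itself a test.

Problem sizes: the default configuration mirrors the study design (12
movement-orientation combinations × 2 recordings × 5 volunteers = 120
recordings, 4 sensor streams each). The test suite runs reduced
configurations (1–3 movements, one volunteer), which exercise every code
path; the acceptance script runs the full 120-recording study.

## Known limitations

* The generator's four simulated sensors differ only in their processing
  path, not in noise structure, so the synthetic study should not (and
  does not) reproduce the published *ranking* of sensors — it validates
  the machinery, and under equal noise the Friedman test correctly finds
  no systematic difference.
* The moving-average amplitude bias described above grows with movement
  amplitude; at 150° excursions the zero-noise median discrepancy would
  approach 1°. It is inherent to a fixed 7-sample kernel applied at two
  different rates.
* Start-offset differences warp the first and last segments (between the
  recording edge and the nearest peak), because segment-wise resampling
  assumes corresponding segments span the same movement phase. The middle
  segment — peaks to peaks — is exact. This mirrors the behaviour of the
  original peak-anchored procedure.
* Euler/Cardan three-DoF decompositions, velocities and accelerations,
  Bland–Altman and ICC analyses are out of scope.
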