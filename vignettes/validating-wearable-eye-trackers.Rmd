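---
title: "Validating wearable eye-tracker data quality with a fiducial-marker poster"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating wearable eye-tracker data quality with a fiducial-marker poster}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazeval)
```

## The measurement model

A wearable eye tracker reports gaze as pixel coordinates in its scene
camera's video. To validate such a recording, the participant fixates known
targets on a printed poster; the inaccuracy for a target is the angle
$\alpha$ at the eye between the reported gaze direction and the direction
to the target. Two distances must therefore be known at every moment: where
the gaze landed on the poster, and where the eye was. Both come from the
poster's array of square fiducial (ArUco) markers of known size and layout.

**Poster frame.** All geometry lives in millimetres on the poster plane:
origin at the centre of the 3×3 target grid, $x$ rightward, $y$ downward,
$z$ into the poster, so a viewer stands at negative $z$. The default poster
places the outer target columns at $\pm 600\tan 10^\circ$ mm and outer rows
at $\pm 600\tan 8.75^\circ$ mm, i.e. the grid subtends $20^\circ \times
17.5^\circ$ from the default assumed viewing position 600 mm out — roughly
an arm's length, the distance at which operators are told to position the
participant. The top-left target is red and starts the reading-order
scanpath; the other eight are blue.

**Marker layout.** Only two properties of the printed marker array are
normative: each marker side is 41.9 mm, and the horizontal extent from the
left edge of the left-most marker column to the right edge of the
right-most column is 356.0 mm — this is the span an operator measures to
verify print scale (`check_print_scale()`), since printers routinely
rescale. The count and arrangement are otherwise free; this package's
default interleaves a 4×4 grid of markers (dictionary ids 0–15, columns and
rows at $\pm 52.35$ and $\pm 157.05$ mm) with the target grid, which
satisfies the span constraint, keeps every frame's field of view populated
with markers, and leaves clearance around every target. Any other layout
can be supplied as a JSON poster file.

**Gaze mapping.** For each video frame, the corner correspondences of all
detected markers (poster mm ↔ image px) are pooled into one homography
estimated by the normalized direct linear transform. Pooling across markers
is preferred over averaging per-marker homographies: with 16 markers a
frame contributes 64 corners and the estimate is correspondingly stabler.
When a camera calibration is available, corners and gaze pixels are first
undistorted (Brown–Conrady model, inverted by Newton iteration), so the
homography relates the poster to an ideal pinhole image; without a
calibration the homography is estimated on raw pixels and the distortion is
absorbed as local approximation error. Gaze is mapped through the inverse
homography; frames without detections are bridged by the nearest-in-time
geometry up to 100 ms (nearest-neighbour, because interpolating matrix
entries is not projectively sound), and longer dropouts propagate as
missing samples with a reason code.

**Viewing position.** Two modes, selected per analysis:

* `fixed_distance` — the eye is assumed at $(0, 0, -d)$ with $d$ the
  configured perpendicular distance (default 600 mm). Simple, no
  calibration needed, but wrong whenever the participant stands elsewhere.
* `pose_estimated` — per frame, $K^{-1}H$ is decomposed into
  $[r_1\, r_2\, t]$; the scale is fixed by the mean norm of the first two
  columns, the sign by putting the plane in front of the camera, and the
  rotation is projected to the nearest orthonormal matrix by SVD. The
  camera position in the poster frame is $-R^\top t$. The eye is equated
  with the scene-camera optical centre; no eye–camera offset is applied
  (the offset is a few centimetres, and the paper-level measures are
  ratios of much larger distances — but the design leaves room to add a
  configurable offset).

"Viewing distance" reported per target is the Euclidean distance from the
eye to that target; the perpendicular distance is what the pose traces
(see the sway-trajectory test, which recovers a 600 ± 100 mm oscillation
to within 1 mm on noiseless frames).

## Fixation classification

The classifier follows the two-means-clustering design of the I2MC family,
adapted to the 50–120 Hz rates of wearable trackers (no multi-rate
downsampling cascade; one scale suffices there). Missing runs up to 100 ms
are linearly interpolated first (interpolated samples are flagged: they
participate in clustering but never in centroids or precision). Every
200 ms window (step one sample, skipped if it touches a longer gap or has
fewer than four samples) is split into two clusters by Lloyd's algorithm,
initialized with the means of the window's two temporal halves. Samples
flanking a cluster-label transition accumulate weight $1/k$, where $k$ is
the number of transitions in that window: a saccade is the *single* clean
transition of every window that covers it and approaches weight 1, while
the label flips inside a noisy fixation are many and scattered, so each
sample's share stays small. This per-window normalization matters — an
unnormalized "+1 per transition" variant saturates at realistic noise
levels and loses the saccade/fixation contrast entirely. The per-sample
weights (counts over covering windows) are then smoothed with a 3-point
moving average, the single-scale analogue of I2MC's averaging across time
scales, which damps one-sample noise spikes that would otherwise cut a
fixation in two.

Fixations are maximal runs with smoothed weight at or below
$\mathrm{mean} + \lambda\,\mathrm{SD}$ ($\lambda = 2$); candidates
separated by at most 30 ms of intervening material and at most $0.7^\circ$
of angular centroid distance are merged; fixations shorter than 40 ms are
dropped. With these defaults, scripted nine-dwell scanpaths at 50 Hz with
per-axis noise up to $\sigma = 0.3^\circ$ are segmented into exactly nine
fixations with onsets within one sample (20 ms) of ground truth, across 30
seeds. The classifier is deliberately a clean, fully specified variant
rather than a line-for-line port; `classify_fixations()` is the single
entry point, so a different classifier can be substituted behind the same
interface.

## Matching and measures

Per target, the nearest fixation in poster space with duration ≥ 50 ms is
selected; all (target, eligible fixation) pairs are sorted by centroid
distance and assigned greedily, so the assignment is injective and the
resolution order when targets compete for a fixation is globally
nearest-first. Unmatched targets are reported as missing, never imputed.

* **Accuracy**: angle between eye→centroid and eye→target, with the
  fixation's eye position taken as the component-wise median of its member
  samples' (estimated or assumed) eye positions — robust to pose jitter.
* **Precision**: per member sample $i$, the angular offset
  $(\Delta\mathrm{az}_i, \Delta\mathrm{el}_i)$ is the Fick-angle difference
  between the directions from that sample's own eye position to the gaze
  point and to the target (azimuth $= \operatorname{atan2}(x, z)$,
  elevation $= \operatorname{atan2}(-y, \sqrt{x^2 + z^2})$). Then
  RMS-S2S $= \sqrt{\overline{\Delta\mathrm{az}^2 + \Delta\mathrm{el}^2}}$
  over the $n - 1$ successive differences, and STD
  $= \sqrt{\mathrm{var}(\mathrm{az}) + \mathrm{var}(\mathrm{el})}$ with
  population ($1/n$) variances. For white angular noise of per-axis SD
  $\sigma$ these converge to $2\sigma$ and $\sigma\sqrt 2$; their ratio
  $\sqrt 2$ is a useful diagnostic (drift pushes it below, anti-correlated
  jitter above), and the tests assert all three behaviours.
* **Data loss**: percent of missing gaze samples over the episode (not
  over matched fixations only — so blinks and tracking dropouts during
  saccades count too, matching how loss is reported for stationary
  trackers).
* **Gaze range**: per matched fixation, the mean gaze *pixel* is
  undistorted and back-projected into a camera-frame direction; the range
  is max − min azimuth and elevation across fixations. It separates the
  "eyes only" strategy (range = angular size of the grid, $20^\circ \times
  17.5^\circ$ at 600 mm) from "nose pointing" (range → 0°), which is why
  it is worth reporting alongside accuracy.
* **Fixed-distance error ratio**: accuracy under the assumed position
  divided by accuracy under the estimated position, × 100%. For gaze
  landing $r$ mm from a central target it is
  $100\,\arctan(r/d_{assumed}) / \arctan(r/d_{physical})$ — ≈ 133% for a
  participant at 800 mm analysed at an assumed 600 mm, which the end-to-end
  test reproduces within 2%.

## The simulator, and what passing tests do and do not show

`simulate_recording()` generates the exact study conditions of the standard
instruction: nine 1 s dwells in reading order at 50 Hz, eye static at the
assumed position, camera aimed at the poster centre. Inaccuracy is injected
as a constant Fick-angle offset, imprecision as white per-axis angular
noise ($\sigma$ in degrees — applied in angle space so recovery is
distance-independent), data loss as Bernoulli dropout, detector error as
Gaussian corner jitter. Saccades are instantaneous single-sample jumps.
Ground truth is emitted per sample and the recording is bit-reproducible
under a fixed seed.

Because noise is injected in Fick angles, a pure-azimuth offset $\delta$ is
recovered as $\delta\cos(\mathrm{el})$ at off-axis targets (at most
0.023° below $\delta$ for $\delta = 2^\circ$ on this poster) — an inherent
property of the angle parameterization, not an estimation error.

What the simulator does **not** emulate: real saccade kinematics and
post-saccadic oscillations, smooth pursuit, blink-shaped loss runs,
eye–camera parallax, rolling shutter, motion blur and marker occlusion
patterns, and correlated (drifting) noise. Passing parameter-recovery tests
therefore demonstrates that the *measurement chain* is unbiased and
correctly scaled under its own model; it does not certify behaviour on any
particular device's artefacts.

## Numerical choices and problem sizes

Homography estimation uses Hartley normalization and rejects degenerate
configurations via the ratio of the two smallest singular values;
noiseless correspondences reproduce held-out points to below $10^{-6}$ px
and camera positions to below 0.1 mm over randomized poses with yaw/pitch
up to 45°. Undistortion is a Newton solve (quadratic convergence; the
fixed-point form diverges near the frame corners for $|k_1| \ge 0.3$).
`angle_between()` clamps the normalized dot product before `acos`. Episode
intervals are half-open `[start, end)`; timestamps are float milliseconds.
Two-means degenerate cases (all points identical, or an emptied cluster)
yield a single label, i.e. no transition, so constant input produces weight
0 everywhere and one full-span fixation.

The test suite runs its stochastic checks at deliberately desk-sized
problems chosen to keep estimator variance well inside the asserted
tolerances: 450-sample recordings (nine 1 s dwells at 50 Hz), 20 seeds for
the noise-recovery means, 30 seeds for classifier dwell-count recovery, 100
random poses for the geometry oracle. These sizes are the package's own
test design; all pipeline code is size-agnostic.

## Known limitations

Mode-1 (`fixed_distance`) results inherit the full error of the assumed
position; the error ratio above quantifies it and pose mode should be
preferred whenever a calibration exists. The classifier is tuned for
wearable-rate data; at 250 Hz+ a downsampling cascade would be worth
adding. Marker detection itself (running ArUco over video) is outside the
tested core — recordings enter as CSV of per-frame corner detections, and
any detector that outputs corners in the fixed top-left/top-right/
bottom-right/bottom-left order can feed the pipeline. XLSX export is not
provided; summaries are CSV.
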