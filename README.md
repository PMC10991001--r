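# gazeval

Data-quality validation for wearable eye trackers using a printed
fiducial-marker poster.

## The problem

Head-mounted (wearable) eye trackers report gaze as a point in the video of
a forward-facing scene camera. Quantifying how good that signal is —
**accuracy** (how far reported gaze lands from what the participant actually
fixated), **precision** (how much the signal jitters), and **data loss**
(how many samples are invalid) — requires fixation targets at a *known*
position relative to the eye, which field experiments rarely have. The
standard solution is a poster carrying fixation targets plus an array of
ArUco fiducial markers of known geometry: the markers let software recover,
frame by frame, both where on the poster the participant is looking and
where the participant is standing.

`gazeval` implements that measurement chain end to end:

1. **Gaze mapping** — per video frame, the detected marker corners (known
   millimetre positions on the poster, observed pixel positions in the
   scene image) give a plane-to-image homography `H`; gaze pixels are
   undistorted and mapped through `H⁻¹` onto the poster plane.
2. **Viewing position** — either *assumed* (a fixed perpendicular distance,
   default 600 mm, eye in front of the poster centre), or *estimated* each
   frame by decomposing `K⁻¹H` into the planar camera pose when the scene
   camera's calibration `K` is available.
3. **Fixation classification** — an I2MC-style classifier: sliding-window
   two-means clustering of the poster-plane gaze positions; samples at
   cluster transitions accumulate weight, and low-weight runs become
   fixations.
4. **Target matching** — for each of the nine fixation targets, the nearest
   fixation at least 50 ms long, injectively (no fixation serves two
   targets).
5. **Measures** — per target:
   - accuracy `α = ∠(g − e, t − e)`, the angle at the eye `e` between the
     fixation's mean gaze position `g` on the poster and the target `t`;
   - precision as RMS-S2S `√(mean(Δθ²))` over successive angular
     sample-to-sample displacements, and as STD
     `√(var(azimuth) + var(elevation))` of the angular offsets;
   - plus episode-level data loss (% missing samples) and the horizontal /
     vertical **gaze range** (max − min gaze direction in the camera frame
     across matched fixations; 20° × 17.5° for a perfectly still head at
     600 mm, shrinking toward 0° when the head does the pointing).

A synthetic-recording simulator with exact ground truth (known offset,
noise, data loss, head trajectory) closes the loop and is used throughout
the tests.

## Worked example

Simulate a participant standing 600 mm from the default poster, fixating
the nine targets in reading order for 1 s each, with a 1.0°/0.3°
(azimuth/elevation) calibration offset, 0.15° RMS-per-axis angular noise and
5% data loss — then measure the recording as if it came off a device:

```r
library(gazeval)

sim <- simulate_recording(simulation_config(
  offset_deg = c(1, 0.3), noise_sigma_deg = 0.15, loss_prob = 0.05, seed = 42))

dq <- compute_data_quality(sim$recording, mode = "pose_estimated")
summarize_data_quality(list(demo = dq), average_over_targets = TRUE)
```

```
  accuracy_deg rms_s2s_deg std_deg data_loss_percent gaze_range_h_deg gaze_range_v_deg
1         1.03       0.295   0.205                 4               20             17.5
```

Reading the numbers: the recovered inaccuracy 1.03° matches the injected
offset magnitude `√(1² + 0.3²) = 1.044°`; RMS-S2S ≈ 0.30° is the expected
`2σ = 0.30°` for white angular noise and STD ≈ 0.21° the expected
`σ√2 = 0.212°`; data loss 4% is the realized Bernoulli(0.05) rate over 450
samples; and the gaze range equals the 20° × 17.5° angular size of the
target grid, as it must for a still head. Per-target rows (drop
`average_over_targets`) additionally report each target's viewing distance
and sample count.

The same chain is available as a project workflow for batches of real
recordings — `project_init()`, `project_import()`, `project_annotate()`
(which episodes of each recording contain a validation),
`project_process()`, `project_export()` — with a thin command-line wrapper
in `inst/cli/gazeval.R`.

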