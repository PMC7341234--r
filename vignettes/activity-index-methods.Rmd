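---
title: "Measuring broiler activity from frame differences: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring broiler activity from frame differences: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The activity index

The activity index (AI) is a classic precision-livestock-farming statistic:
it quantifies how much a group of animals moved between two video frames,
without tracking individuals and without estimating motion direction. Given
grayscale frames $I(x, y, t)$, a pixel is *changed* when its intensity
difference across the frame pair exceeds a threshold $\tau$:

$$
I_a(x, y, t) =
\begin{cases}
1 & \text{if } |I(x, y, t) - I(x, y, t-\Delta)| > \tau \\
0 & \text{otherwise,}
\end{cases}
$$

and the activity index of the pair is the changed-pixel count normalised by
the number of bird-representative pixels in the earlier frame,

$$
\mathrm{AI}(t) = \frac{\sum_{x,y} I_a(x, y, t)}{S(t - \Delta)}.
$$

Normalising by $S$ compensates for the number and apparent size of the birds
in the region of interest. AI is dimensionless and can exceed 1: a bird
displaced by more than its own length changes roughly twice its own area of
pixels.

Two details of the thresholding rule deserve attention:

* **Strict inequality.** A difference exactly equal to $\tau$ does not count
  as motion. This matches the rule as classically written and makes the
  changed-pixel count non-increasing in $\tau$, a property the tests check.
* **Sidedness.** The rule is often written one-sided
  ($I(t) - I(t-\Delta) > \tau$), which only detects pixels that *brighten*
  — when bright birds move over dark litter, the pixels a bird vacates
  darken and are missed. `activityindex` defaults to the symmetric
  (`"absolute"`) form, which is standard motion-detection practice, and
  offers `mode = "onesided"` to reproduce the literal one-sided rule. Both
  are tested; for comparisons across sampling intervals the choice barely
  matters because it scales both sides of every ratio similarly.

Differences are computed in a signed numeric domain. This matters: frames
are unsigned 8-bit images, and differencing them in unsigned arithmetic is
the classic frame-differencing bug (wraparound turns a $-5$ into $251$).

## Threshold calibration

$\tau$ is calibrated per clip as a fixed fraction (default 0.15) of the
maximal pixel intensity observed over the clip's leading empty-background
frames (default 20). The empty background exposes the sensor-noise and
lighting floor, so a threshold above it suppresses spurious motion from
electrical noise and flicker. Whether the "maximal intensity" should be read
over the calibration frames only or over the whole clip is ambiguous in the
field literature; `calibrate_threshold()` uses the calibration frames by
default and offers `use_all_frames = TRUE` for the other reading.

## Estimating S(t): bird-pixel segmentation

How $S(t)$ is obtained is generally left unspecified in AI studies. The
package's choice uses only in-clip information, mirroring the threshold
calibration: the background reference is the per-pixel **median** of the
calibration frames (robust to occasional outliers), a pixel is
bird-representative when $|I - \mathrm{background}| >$ `seg_threshold`
(defaulting to the same $\tau$), and 4-connected components smaller than
`min_blob_area` (default 4 px) are discarded as noise specks. Connected
components come from `EBImage::bwlabel()`; the test suite validates the blob
filtering against a hand-written flood-fill oracle. On synthetic noise-free
frames this estimator recovers the true bird-pixel count exactly, and within
2% when sensor noise is at a third of the calibrated threshold — the
acceptance suite checks both.

When a frame contains no bird-representative pixels, $S(t-\Delta) = 0$ and
AI is undefined: the sample is emitted as `NA` with a warning, never as a
division by zero, and downstream window sums skip and count missing samples.

## Sampling intervals, cumulative windows and ratios

The central design question the pipeline addresses is the choice of
*sampling time interval* $\Delta$ — the time between the two frames that are
differenced. A 25 fps camera gives $\Delta = 0.04$ s at full frame rate;
longer intervals (0.2, 1, 10, 60, 300 s) discard intermediate frames,
reducing the processing workload proportionally (0.2 s keeps one frame in
five: an 80% reduction). But longer intervals miss *transient behaviors* —
turning, bobbling, preening, shaking — that complete within the interval and
leave no trace at its endpoints, so AI is progressively underestimated.

`subsample()` keeps frames at indices $0, k, 2k, \dots$ with
$k = \Delta \times \mathrm{fps}$ (which must be a whole number), preserving
source timestamps. AI computed on a subsampled sequence is identical to AI
computed on the retained pairs of the full sequence, a property the tests
assert.

Because per-pair AI values at different intervals are not comparable (there
are 25 times more of them at 0.04 s than at 1 s), the unit of analysis is
the **cumulative AI**: the plain sum of all AI samples whose current-frame
time falls in a fixed window (default 300 s, half-open $[start, end)$).
Only complete windows are kept — a 56-min clip yields exactly 11. A complete
window that happens to contain no sample (possible when $\Delta$ is
comparable to the window length) is reported with zero samples and zero
cumulative AI rather than dropped, so every interval covers the same window
set and per-window ratios stay paired.

Intervals are compared through the per-window ratio
$100 \times \mathrm{cumAI}_\Delta / \mathrm{cumAI}_{0.04}$, averaged per
interval (*mean of ratios*). The alternative — the ratio of mean cumulative
AIs — is also reported (`ratio_of_means_pct`), because published tables of
this design are ambiguous about which was used and the two differ when
windows are heterogeneous; the mean-of-ratios is labelled primary since it
is the statistic for which a per-interval SEM is well defined. Windows with
zero baseline cumulative AI are excluded from ratios and counted.

Group summaries (`summarize_groups()`) report n, mean cumulative AI and the
plain standard error $sd/\sqrt{n}$ per group; least-squares (model-adjusted)
means are deliberately out of scope — any GLM machinery in base R can be
applied to the `windows` tibble directly.

## The synthetic flock simulator

No public video accompanies this analysis problem, so the package ships a
seeded simulator whose output has the statistical structure the pipeline
assumes, plus exact ground truth. A scene is a square arena of textured
litter (static per-pixel Gaussian texture around `background_intensity`)
over which `n_birds` bright, hard-edged ellipses move. Hard edges are a
deliberate rendering choice: with no anti-aliasing, the per-frame bird masks
are exact, so ground-truth bird-pixel counts and changed-pixel counts are
integers the pipeline can be held to.

Behaviour has three ingredients:

* **Locomotion**: a correlated random walk — per-frame heading perturbation
  (sd `heading_sd` radians) at speed `speed_mean`, with arena walls
  reflecting the path. The ellipse is oriented along the heading.
* **Resting**: alternating rest/move bouts (geometric dwell times, mean rest
  bout `rest_bout_s`) tuned so the long-run stationary fraction equals
  `resting_prob`. Resting birds are pixel-frozen.
* **Transient events**: Poisson-arriving bursts (`transient_rate` per bird
  per minute, duration `transient_duration` seconds, sub-second by design)
  that jitter a stationary bird's orientation in place. These are the
  movements long sampling intervals fail to capture: a burst that starts and
  ends between two sampled frames leaves the endpoint frames nearly
  identical.

The first `empty_frames` (default 20) frames are bird-free, providing the
empty background that threshold calibration and segmentation assume.
`split_calibration()` separates them and re-zeroes the analysis timestamps,
snapping to the frame grid so floating-point residue cannot shift a sample
across a window boundary.

Default parameters and their rationale (all simulator choices, not field
measurements): the arena defaults to 200 px spanning 0.71 m (0.00355 m/px)
at 25 fps, matching the analysis ROI geometry; ellipse semi-axes (30, 18) px
give a bird ~21 cm long, a mid-grow-out body size at that scale; 6 birds put
~25% of the ROI under bird pixels, a plausible crowding level; walking speed
0.05 m/s, resting fraction 0.5 and 3 transient events/bird/min represent
unremarkable daytime behaviour; litter texture sd 8 and sensor noise sd 2
put the calibrated $\tau$ (~15 intensity units) well above $3\times$ the
noise sd, so noise alone cannot trigger the motion rule (the pipeline warns
if a configuration violates this).

`age_preset()` maps grow-out weeks 1–7 onto a single activity scalar that
scales speed down and resting up with age — enough to generate
age-structured summary tables, with no claim of biological calibration.

`continuous_motion_config()` is the preset for studying interval effects
under pure locomotion: no resting, no transient events, and a small heading
perturbation (0.02 rad/frame) so paths are near-straight over sub-second
horizons. The small value is principled, not cosmetic: in this framework
*turning is part of the transient repertoire*, which the preset excludes by
definition, so its walk should contain as little incidental rotation as a
smooth walk allows. Under such motion the expected changed-pixel count is
nearly linear in displacement until the displacement approaches the body
size, so cumulative AI at 0.2 s stays within a few percent of the 0.04-s
baseline, while at 300 s each window contributes a single saturated pair and
recovers only a tiny fraction of baseline activity — the qualitative pattern
the pipeline exists to expose.

### What the simulator does and does not emulate

It reproduces the features the pipeline's correctness depends on: bright
birds on darker textured litter, additive sensor noise below threshold,
continuous and sub-second motion, resting animals, exact ground truth, and
seeded determinism (integer intensities are bit-identical across platforms
given a seed). It does **not** emulate photorealistic plumage, lens
distortion (a user-supplied remap hook is accepted at load time instead),
shadows, lighting drift, birds entering/leaving the ROI, feeder/drinker
objects, or contact interactions. Passing tests on synthetic scenes
therefore validate the *computational* pipeline, not the field accuracy of
segmentation on real litter.

## Numerical choices

* Grayscale conversion: ITU-R BT.601 luma, rounded half-up (base `round()`
  is half-to-even and platform-tempting; half-up is deterministic).
* Coordinates: 0-based, `[x0, x0 + width)` half-open ROIs; frames are
  `[row = y, column = x]` integer matrices.
* Timestamps always derive from file order and fps, never file metadata.
* Window assignment: current-frame time, half-open `[start, end)`; trailing
  partial windows dropped.
* Degenerate inputs: all-zero calibration frames, out-of-bounds ROIs,
  non-integer subsampling strides, missing baseline intervals and
  infeasible bird packings all fail fast with named errors; $S = 0$ pairs
  degrade to `NA` with a warning instead.

## Problem sizes used by the test and acceptance suites

The simulation-backed checks run on scaled-down scenes chosen as the
package's own desk-scale study conditions: unit tests use a 96-px arena
(0.71 m at 0.0074 m/px), 3–5 birds and 1–60 s clips; the interval-sweep
experiments use a 64-px arena (0.71 m at 0.0111 m/px), 4 birds and 630-s
clips — two complete 300-s windows, so even the 300-s interval contributes a
sample — over 20 seeded replicates in the test suite and 8 in the
acceptance script. At these sizes the full suite completes in a few minutes
on one CPU while leaving thousands of frame pairs per replicate, enough for
stable interval ratios.

## Limitations

* AI is a group-level, direction-free statistic: it cannot separate one
  fast bird from many slow ones, and optical-flow or per-bird tracking
  questions are out of scope.
* The printed AI magnitudes of any particular field study depend on scene
  scale, bird count and segmentation details; without the original video
  only the *structure* of such results (interval ordering, ratio decay,
  window counts) is reproducible, and that is what the acceptance checks
  assert.
* Segmentation assumes a static background brighter-or-darker than the
  birds by more than the threshold; litter darkening over a grow-out or
  moved bedding would require re-calibration per clip (which the per-clip
  design provides) but is not simulated.
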