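# activityindex

Frame-differencing activity analysis for broilers (and other
group-housed animals) monitored by fixed top-view cameras — a
precision-livestock-farming pipeline for the **activity index (AI)**.

Given grayscale frames `I(x, y, t)` from a region of interest, a pixel is
*changed* when its intensity difference across a frame pair exceeds a
calibrated threshold τ:

    I_a(x, y, t) = 1  if |I(x, y, t) − I(x, y, t−Δ)| > τ,  else 0

and the activity index of the pair is the changed-pixel count normalised by
the bird-representative pixel count of the earlier frame:

    AI(t) = Σ_{x,y} I_a(x, y, t) / S(t−Δ)

τ is calibrated per clip as 15% of the maximal intensity of the clip's
leading empty-background frames; `S` comes from thresholded deviation
against a median background reference with small blobs removed. Because
per-pair AI values at different sampling intervals Δ are not comparable, the
unit of analysis is the **cumulative AI** per 300-s window, and intervals
are compared as per-window percentage ratios against the full-frame
(0.04 s at 25 fps) baseline. The scientific point the pipeline exposes:
sub-second *transient* movements (turning, preening, shaking) vanish from
frames sampled further apart than the movement lasts, so AI decays — and its
accuracy with it — as the sampling interval grows, while a 0.2-s interval
keeps AI close to baseline at 20% of the processing workload.

The package covers the whole chain: frame I/O and ROI cropping → threshold
calibration → motion masks → bird segmentation → AI series → temporal
subsampling → cumulative windows → interval ratios and grouped mean ± SEM
summaries — plus a seeded **synthetic flock simulator** (moving bird-shaped
ellipses on textured litter with sensor noise, resting bouts and transient
bursts) with exact ground truth, so everything is testable without video.

## Worked example

Simulate a one-minute clip of three birds and compare sampling intervals:

```r
library(activityindex)

cfg <- flock_sim_config(arena_px = 96, scale = 0.71/96, n_birds = 3,
                        bird_axes_px = c(12, 7), duration = 60, seed = 42)
sim <- simulate_flock(cfg)
sim$frames
#> <frame_sequence> 1520 frame(s), 96x96 px, 25 fps, 0.00-60.76 s [sim-seed42]

res <- analyze_clip(sim$frames, threshold_config(calibration_frames = 20),
                    intervals = c(0.04, 0.2, 1, 10), window = 30)
res$tau
#> [1] 16.2

ratio_to_baseline(res$windows, baseline = 0.04)
#>   interval_s n_windows mean_cumulative_ai   sem ratio_pct
#> 1       0.04         2             29.373 4.447    100.00
#> 2       0.20         2             17.833 2.907     60.60
#> 3       1.00         2             13.674 1.945     46.62
#> 4      10.00         2              4.498 1.322     16.37
```

Reading the output: τ = 16.2 is 15% of the brightest pixel seen in the 20
empty calibration frames. Each row summarises the two complete 30-s windows
of the clip at one sampling interval: `mean_cumulative_ai` is the mean over
windows of the summed per-pair AI, `sem` its standard error, and `ratio_pct`
the mean per-window percentage of the 0.04-s baseline. With this flock
resting half the time and moving in bursts, already the 0.2-s interval
misses ~40% of the activity, and 10-s sampling sees barely a sixth of it —
the decay-with-interval pattern that motivates full-frame (or near
full-frame) sampling.

Real footage enters the same way via `load_sequence("frames_dir/", 25)`
(PNG/TIFF frames, lexicographic = temporal order), `crop(seq, roi(...))`,
and `run_activity()` with a YAML config; `inst/cli/activityindex.R` wraps
the stages as `simulate` / `analyze` / `sweep` / `summarize` subcommands.

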