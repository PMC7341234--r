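#' Synthetic flock simulator configuration
#'
#' Parameters of the seeded top-view scene generator: bright bird-shaped
#' ellipses moving over a darker, textured litter background with additive
#' sensor noise. The geometry defaults mirror the analysis ROI (200 px
#' spanning 0.71 m at 25 fps); the behavioural defaults are simulator
#' choices representing a mid-grow-out commercial flock, not measured
#' values. Birds alternate between resting bouts and locomotion (a
#' correlated random walk), and sub-second transient events (turning,
#' preening, shaking and the like) jitter a bird's orientation in place
#' without displacing it — the class of movement that long sampling
#' intervals fail to capture.
#'
#' @param arena_px Frame side in pixels (frames are square).
#' @param scale Meters per pixel (see [pixel_scale()]).
#' @param frame_rate Frames per second.
#' @param duration Seconds of bird footage (excluding calibration frames).
#' @param n_birds Number of birds.
#' @param bird_axes_px Ellipse semi-axes (along-heading, across-heading), px.
#' @param bird_intensity,background_intensity Mean intensities; birds must be
#'   brighter than the litter.
#' @param texture_sd Standard deviation of the static litter texture
#'   (per-pixel Gaussian, frozen over time), intensity units.
#' @param speed_mean Walking speed of a moving bird, m/s.
#' @param resting_prob Long-run fraction of time a bird is stationary.
#' @param rest_bout_s Mean duration of one resting bout, seconds.
#' @param heading_sd Per-frame heading perturbation while walking, radians.
#' @param transient_rate Transient events per bird per minute.
#' @param transient_duration Duration of one transient event, seconds
#'   (sub-second by design).
#' @param transient_heading_sd Per-frame orientation jitter during a
#'   transient event, radians.
#' @param noise_sd Additive Gaussian sensor noise, intensity units. Keep
#'   `3 * noise_sd` below the calibrated motion threshold so noise alone
#'   cannot flag motion (true for these defaults; the pipeline warns
#'   otherwise).
#' @param empty_frames Number of leading bird-free frames emitted for
#'   threshold/background calibration.
#' @param max_intensity Intensity ceiling (255 = 8-bit).
#' @param seed Integer seed; the whole simulation is reproducible from it.
#' @return An object of class `flock_sim_config`.
#' @export
flock_sim_config <- function(arena_px = 200L,
                             scale = 0.71 / 200,
                             frame_rate = 25,
                             duration = 60,
                             n_birds = 6L,
                             bird_axes_px = c(30, 18),
                             bird_intensity = 200,
                             background_intensity = 70,
                             texture_sd = 8,
                             speed_mean = 0.05,
                             resting_prob = 0.5,
                             rest_bout_s = 5,
                             heading_sd = 0.1,
                             transient_rate = 3,
                             transient_duration = 0.3,
                             transient_heading_sd = 0.6,
                             noise_sd = 2,
                             empty_frames = 20L,
                             max_intensity = 255L,
                             seed = 1L) {
  cfg <- list(
    arena_px = as.integer(arena_px), scale = scale, frame_rate = frame_rate,
    duration = duration, n_birds = as.integer(n_birds),
    bird_axes_px = bird_axes_px, bird_intensity = bird_intensity,
    background_intensity = background_intensity, texture_sd = texture_sd,
    speed_mean = speed_mean, resting_prob = resting_prob,
    rest_bout_s = rest_bout_s, heading_sd = heading_sd,
    transient_rate = transient_rate, transient_duration = transient_duration,
    transient_heading_sd = transient_heading_sd, noise_sd = noise_sd,
    empty_frames = as.integer(empty_frames),
    max_intensity = as.integer(max_intensity), seed = as.integer(seed)
  )
  stopifnot(
    cfg$arena_px >= 8, cfg$scale > 0, cfg$frame_rate > 0, cfg$duration > 0,
    cfg$n_birds >= 0, length(cfg$bird_axes_px) == 2, all(cfg$bird_axes_px > 0),
    cfg$bird_axes_px[1] >= cfg$bird_axes_px[2],
    cfg$speed_mean >= 0, cfg$resting_prob >= 0, cfg$resting_prob <= 1,
    cfg$rest_bout_s > 0, cfg$heading_sd >= 0, cfg$transient_rate >= 0,
    cfg$transient_duration > 0, cfg$noise_sd >= 0, cfg$texture_sd >= 0,
    cfg$empty_frames >= 1
  )
  if (cfg$bird_intensity <= cfg$background_intensity) {
    stop("birds must be brighter than the background")
  }
  margin <- ceiling(max(cfg$bird_axes_px)) + 1
  if (cfg$n_birds > 0 && cfg$arena_px - 2 * margin < 2) {
    stop("infeasible packing: a bird does not fit inside the arena")
  }
  ellipse_area <- pi * cfg$bird_axes_px[1] * cfg$bird_axes_px[2]
  if (cfg$n_birds * ellipse_area > 0.55 * cfg$arena_px^2) {
    stop("infeasible packing: birds cannot fit in the arena at this density")
  }
  structure(cfg, class = "flock_sim_config")
}

#' Continuous-locomotion behaviour preset
#'
#' A configuration in which birds walk continuously: no resting bouts and no
#' transient events, with a small per-frame heading perturbation so paths are
#' near-straight over sub-second horizons (turning belongs to the transient
#' repertoire, which this preset excludes). Useful for studying how sampling
#' interval affects the activity index when all motion is smooth locomotion.
#'
#' @param ... Overrides passed to [flock_sim_config()].
#' @return A [flock_sim_config()].
#' @export
continuous_motion_config <- function(...) {
  args <- list(resting_prob = 0, transient_rate = 0, heading_sd = 0.02)
  override <- list(...)
  args[names(override)] <- override
  do.call(flock_sim_config, args)
}

#' Age-dependent activity preset
#'
#' Maps a grow-out week (1-7) to a single activity scalar that scales walking
#' speed down and resting fraction up as birds age and gain weight. This is a
#' deliberately simple emulation for generating age-structured summaries; it
#' claims no biological calibration.
#'
#' @param cfg A [flock_sim_config()] to modify.
#' @param week Grow-out week, 1-7.
#' @return The modified [flock_sim_config()].
#' @export
age_preset <- function(cfg, week) {
  stopifnot(inherits(cfg, "flock_sim_config"), is_count(week),
            week >= 1, week <= 7)
  act <- c(1.0, 0.85, 0.7, 0.55, 0.45, 0.4, 0.38)[week]
  args <- unclass(cfg)
  args$speed_mean <- 0.08 * act
  args$resting_prob <- 1 - 0.65 * act
  do.call(flock_sim_config, args)
}

# fold an unbounded coordinate into [lo, hi] by reflection (triangle wave)
reflect_into <- function(z, lo, hi) {
  rng <- hi - lo
  y <- (z - lo) %% (2 * rng)
  lo + ifelse(y > rng, 2 * rng - y, y)
}

# alternating rest/move bout indicator of length n; stationary long-run
# fraction p with mean rest bout `rest_frames`
rest_indicator <- function(n, p, rest_frames) {
  if (p <= 0) return(rep(FALSE, n))
  if (p >= 1) return(rep(TRUE, n))
  move_frames <- rest_frames * (1 - p) / p
  states <- logical(0)
  resting <- stats::runif(1) < p
  while (length(states) < n) {
    mean_len <- if (resting) rest_frames else move_frames
    len <- stats::rgeom(1, prob = min(1, 1 / mean_len)) + 1L
    states <- c(states, rep(resting, len))
    resting <- !resting
  }
  states[seq_len(n)]
}

# indicator of transient events: Poisson starts at `rate` per minute, each
# lasting `dur_frames` frames
transient_indicator <- function(n, rate, fps, dur_frames) {
  if (rate <= 0) return(rep(FALSE, n))
  p_start <- rate / (60 * fps)
  starts <- which(stats::runif(n) < p_start)
  on <- logical(n)
  for (s in starts) on[s:min(n, s + dur_frames - 1L)] <- TRUE
  on
}

# paint a hard-edged rotated ellipse; returns modified (canvas, mask)
paint_ellipse <- function(canvas, mask, cx, cy, theta, a, b, intensity) {
  h <- max(a, b)
  cols <- max(0, floor(cx - h)):min(ncol(canvas) - 1L, ceiling(cx + h))
  rows <- max(0, floor(cy - h)):min(nrow(canvas) - 1L, ceiling(cy + h))
  dx <- cols - cx
  dy <- rows - cy
  ct <- cos(theta)
  st <- sin(theta)
  lx <- outer(dy * st, dx * ct, "+")
  ly <- outer(dy * ct, -dx * st, "+")
  inside <- (lx / a)^2 + (ly / b)^2 <= 1
  ri <- rows + 1L
  ci <- cols + 1L
  sub <- canvas[ri, ci, drop = FALSE]
  sub[inside] <- intensity
  canvas[ri, ci] <- sub
  msub <- mask[ri, ci, drop = FALSE]
  msub[inside] <- TRUE
  mask[ri, ci] <- msub
  list(canvas = canvas, mask = mask)
}

#' Simulate a top-view flock image sequence with ground truth
#'
#' Renders `empty_frames` bird-free calibration frames followed by
#' `duration * frame_rate` frames of `n_birds` ellipses moving over a static
#' textured litter field. Moving birds follow a correlated random walk
#' (per-frame heading perturbation, reflecting arena walls, centers kept
#' fully inside the arena); resting birds are frozen; transient events rotate
#' a bird in place for a sub-second burst. Intensities are integer, with
#' optional additive Gaussian sensor noise, clipped to the bit depth.
#' Everything is reproducible from `cfg$seed`.
#'
#' @param cfg A [flock_sim_config()].
#' @param return_masks Also return the per-frame ground-truth bird masks
#'   (memory-hungry for long clips; the per-frame pixel counts and per-pair
#'   changed-pixel counts are always returned).
#' @return A list: `frames` (a [frame_sequence()]), `truth` (list with
#'   `bird_pixels` per frame, `changed_pixels` per consecutive pair —
#'   noise-free geometric truth — and optionally `masks`), and `config`.
#' @export
simulate_flock <- function(cfg, return_masks = FALSE) {
  stopifnot(inherits(cfg, "flock_sim_config"))
  set.seed(cfg$seed)
  n_px <- cfg$arena_px
  fps <- cfg$frame_rate
  n_move <- as.integer(round(cfg$duration * fps))
  n_total <- cfg$empty_frames + n_move
  a <- cfg$bird_axes_px[1]
  b <- cfg$bird_axes_px[2]
  margin <- ceiling(max(a, b)) + 1
  lo <- margin
  hi <- n_px - 1 - margin

  texture <- matrix(
    clip(round_half_up(stats::rnorm(n_px^2, cfg$background_intensity,
                                    cfg$texture_sd)),
         0, cfg$max_intensity),
    nrow = n_px
  )

  # per-bird kinematics over the bird-footage frames, fully vectorised:
  # heading = cumulated perturbations (walking: heading_sd; in-place
  # transient: transient_heading_sd; resting: none), position = reflected
  # cumulated steps
  speed_px <- cfg$speed_mean / cfg$scale / fps
  xs <- ys <- hs <- matrix(0, nrow = n_move, ncol = cfg$n_birds)
  dur_frames <- max(1L, as.integer(round(cfg$transient_duration * fps)))
  for (bird in seq_len(cfg$n_birds)) {
    resting <- rest_indicator(n_move, cfg$resting_prob,
                              cfg$rest_bout_s * fps)
    transient <- transient_indicator(n_move, cfg$transient_rate, fps,
                                     dur_frames)
    # a bird with zero walking speed has no locomotion and hence no heading
    # drift; orientation changes then come only from transient events
    moving <- !resting & speed_px > 0
    jitter_sd <- moving * cfg$heading_sd +
      (!moving & transient) * cfg$transient_heading_sd
    heading <- stats::runif(1, 0, 2 * pi) +
      cumsum(stats::rnorm(n_move) * jitter_sd)
    step <- moving * speed_px
    x0 <- stats::runif(1, lo, hi)
    y0 <- stats::runif(1, lo, hi)
    xs[, bird] <- reflect_into(x0 + cumsum(step * cos(heading)), lo, hi)
    ys[, bird] <- reflect_into(y0 + cumsum(step * sin(heading)), lo, hi)
    hs[, bird] <- heading
  }

  frames <- vector("list", n_total)
  bird_pixels <- integer(n_total)
  changed_pixels <- integer(max(0L, n_total - 1L))
  masks <- if (return_masks) vector("list", n_total) else NULL
  empty_mask <- matrix(FALSE, n_px, n_px)
  prev_mask <- empty_mask
  for (f in seq_len(n_total)) {
    canvas <- texture
    mask <- empty_mask
    if (f > cfg$empty_frames && cfg$n_birds > 0) {
      mf <- f - cfg$empty_frames
      for (bird in seq_len(cfg$n_birds)) {
        res <- paint_ellipse(canvas, mask, xs[mf, bird], ys[mf, bird],
                             hs[mf, bird], a, b, cfg$bird_intensity)
        canvas <- res$canvas
        mask <- res$mask
      }
    }
    if (cfg$noise_sd > 0) {
      canvas <- canvas + stats::rnorm(n_px^2, 0, cfg$noise_sd)
    }
    frame <- clip(round_half_up(canvas), 0, cfg$max_intensity)
    storage.mode(frame) <- "integer"
    frames[[f]] <- frame
    bird_pixels[f] <- sum(mask)
    if (f > 1L) changed_pixels[f - 1L] <- sum(xor(mask, prev_mask))
    if (return_masks) masks[[f]] <- mask
    prev_mask <- mask
  }

  seq <- frame_sequence(
    frames, frame_rate = fps,
    source_id = sprintf("sim-seed%d", cfg$seed),
    max_intensity = cfg$max_intensity
  )
  truth <- list(bird_pixels = bird_pixels, changed_pixels = changed_pixels)
  if (return_masks) truth$masks <- masks
  list(frames = seq, truth = truth, config = cfg)
}

#' Analyse a simulated (or real) clip at one interval
#'
#' Shared single-clip pipeline: split off the calibration frames, calibrate
#' tau and the segmentation background, subsample, compute the activity
#' series, and (optionally) accumulate it into windows.
#'
#' @param seq A [frame_sequence()] whose leading frames are empty background.
#' @param threshold_cfg A [threshold_config()]; its `calibration_frames`
#'   must be the number of leading empty frames.
#' @param intervals Sampling intervals (seconds) to analyse.
#' @param window Cumulative-window length in seconds; `NULL` skips windowing.
#' @param min_blob_area Passed to [calibration_model()].
#' @param roi_label Label carried into the samples.
#' @return A list: `tau`, `model`, `samples` (one tibble, all intervals),
#'   and `windows` (tibble, or `NULL`).
#' @export
analyze_clip <- function(seq, threshold_cfg = threshold_config(),
                         intervals = study_intervals(), window = 300,
                         min_blob_area = 4L, roi_label = "custom") {
  parts <- split_calibration(seq, threshold_cfg$calibration_frames)
  tau <- calibrate_threshold(parts$calibration, threshold_cfg)
  model <- calibration_model(parts$calibration, threshold_cfg,
                             min_blob_area = min_blob_area)
  duration <- length(parts$analysis) / seq$frame_rate
  samples_list <- list()
  windows_list <- list()
  for (iv in intervals) {
    sub <- subsample(parts$analysis, iv)
    samples <- ai_series(sub, model, tau, threshold_cfg$mode,
                         roi_label = roi_label)
    samples$interval_s <- iv
    samples_list[[as.character(iv)]] <- samples
    if (!is.null(window)) {
      windows_list[[as.character(iv)]] <-
        cumulative_windows(samples, window, duration)
    }
  }
  list(
    tau = tau, model = model,
    samples = dplyr::bind_rows(samples_list),
    windows = if (is.null(window)) NULL else dplyr::bind_rows(windows_list)
  )
}

#' Sampling-interval sweep on simulated flocks
#'
#' Runs the full pipeline (simulate, calibrate, subsample at each interval,
#' activity series, cumulative windows) over seeded replicates and compares
#' intervals against the full-frame baseline. Replicate r uses seed
#' `cfg$seed + r - 1`.
#'
#' @param cfg A [flock_sim_config()]; `duration` should cover at least two
#'   windows so the longest interval contributes samples.
#' @param intervals Sampling intervals in seconds (must include the
#'   baseline = the smallest).
#' @param replicates Number of seeded replicates.
#' @param threshold_cfg A [threshold_config()]; `calibration_frames` is
#'   forced to `cfg$empty_frames`.
#' @param window Cumulative-window length in seconds.
#' @param min_blob_area Passed to [calibration_model()].
#' @return A list: `comparison` (per-interval mean cumulative AI, SEM and
#'   ratio-to-baseline, pooled over replicates; see [ratio_to_baseline()]),
#'   `windows` (all windows with a `replicate` column), `tau` (per
#'   replicate).
#' @export
interval_sweep_experiment <- function(cfg, intervals = study_intervals(),
                                      replicates = 1L,
                                      threshold_cfg = threshold_config(),
                                      window = 300, min_blob_area = 4L) {
  stopifnot(inherits(cfg, "flock_sim_config"), is_count(replicates),
            replicates >= 1)
  threshold_cfg <- threshold_config(threshold_cfg$fraction,
                                    cfg$empty_frames, threshold_cfg$mode)
  baseline <- min(intervals)
  windows_list <- vector("list", replicates)
  taus <- numeric(replicates)
  for (r in seq_len(replicates)) {
    args <- unclass(cfg)
    args$seed <- cfg$seed + r - 1L
    cfg_r <- do.call(flock_sim_config, args)
    sim <- simulate_flock(cfg_r)
    res <- tryCatch(
      analyze_clip(sim$frames, threshold_cfg, intervals, window,
                   min_blob_area),
      error = function(e) {
        stop(sprintf("replicate %d (seed %d): %s", r, cfg_r$seed,
                     conditionMessage(e)), call. = FALSE)
      }
    )
    taus[r] <- res$tau
    if (res$tau < 3 * cfg$noise_sd) {
      warning(sprintf(
        "replicate %d: calibrated tau (%.2f) < 3 * noise_sd (%.2f); sensor noise may register as motion",
        r, res$tau, 3 * cfg$noise_sd
      ))
    }
    w <- res$windows
    w$replicate <- r
    windows_list[[r]] <- w
    rm(sim, res)
  }
  windows <- dplyr::bind_rows(windows_list)
  comparison <- ratio_to_baseline(windows, baseline = baseline)
  list(comparison = comparison, windows = windows, tau = taus)
}
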