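#' Threshold calibration settings
#'
#' The motion threshold tau is set to a fraction (study value 0.15) of the
#' maximal pixel intensity observed over the first `calibration_frames`
#' (study value 20) frames of a clip, which show the empty background. This
#' keeps sensor noise and lighting flicker below the motion threshold.
#'
#' @param fraction Fraction of the calibration maximum, in (0, 1).
#' @param calibration_frames Number of leading empty-background frames.
#' @param mode Differencing mode: `"absolute"` flags `|curr - prev| > tau`
#'   (symmetric, the default); `"onesided"` flags only brightening pixels,
#'   `curr - prev > tau`, the thresholded difference exactly as classically
#'   written.
#' @return An object of class `threshold_config`.
#' @export
threshold_config <- function(fraction = 0.15, calibration_frames = 20L,
                             mode = c("absolute", "onesided")) {
  if (!is_number(fraction) || fraction <= 0 || fraction >= 1) {
    stop("`fraction` must lie strictly between 0 and 1")
  }
  if (!is_count(calibration_frames) || calibration_frames < 1) {
    stop("`calibration_frames` must be a positive integer")
  }
  structure(
    list(fraction = fraction,
         calibration_frames = as.integer(calibration_frames),
         mode = match.arg(mode)),
    class = "threshold_config"
  )
}

#' Calibrate the motion threshold from empty-background frames
#'
#' tau = `fraction` times the maximum pixel intensity over the first
#' `calibration_frames` frames (or the whole clip with
#' `use_all_frames = TRUE`).
#'
#' @param seq A [frame_sequence()] whose leading frames show the empty
#'   background.
#' @param cfg A [threshold_config()].
#' @param use_all_frames Take the maximum over the whole clip instead of the
#'   calibration frames only.
#' @return tau, in intensity units (not necessarily integer).
#' @export
calibrate_threshold <- function(seq, cfg = threshold_config(),
                                use_all_frames = FALSE) {
  stopifnot(inherits(seq, "frame_sequence"), inherits(cfg, "threshold_config"))
  n <- cfg$calibration_frames
  if (length(seq) < n) {
    stop(sprintf("sequence has %d frame(s) but %d calibration frames required",
                 length(seq), n))
  }
  frames <- if (use_all_frames) seq$frames else seq$frames[seq_len(n)]
  mx <- max(vapply(frames, max, numeric(1)))
  if (mx <= 0) stop("degenerate calibration: all calibration frames are zero")
  cfg$fraction * mx
}

#' Binary inter-frame motion mask
#'
#' A pixel is flagged as changed when the intensity difference between the
#' current and previous frame exceeds tau (strict inequality). Differences
#' are taken in a signed numeric domain, so unsigned wraparound cannot occur.
#'
#' @param prev,curr Integer matrices of identical dimensions.
#' @param tau Motion threshold in intensity units; see
#'   [calibrate_threshold()].
#' @param mode `"absolute"` (symmetric, default) or `"onesided"`
#'   (brightening only); see [threshold_config()].
#' @param t_prev,t_curr Optional times (seconds) of the two frames.
#' @return An object of class `motion_mask`: `values` (0/1 integer matrix),
#'   `t_prev`, `t_curr`.
#' @export
motion_mask <- function(prev, curr, tau, mode = c("absolute", "onesided"),
                        t_prev = NA_real_, t_curr = NA_real_) {
  mode <- match.arg(mode)
  if (!is.matrix(prev) || !is.matrix(curr) || !identical(dim(prev), dim(curr))) {
    stop("`prev` and `curr` must be matrices of identical dimensions")
  }
  if (!is.na(t_prev) && !is.na(t_curr) && t_curr <= t_prev) {
    stop("`t_curr` must exceed `t_prev`")
  }
  values <- diff_exceeds(prev, curr, tau, mode)
  storage.mode(values) <- "integer"
  structure(list(values = values, t_prev = t_prev, t_curr = t_curr),
            class = "motion_mask")
}

# shared primitive behind motion_mask() and ai_series(): logical matrix of
# pixels whose signed difference exceeds tau
diff_exceeds <- function(prev, curr, tau, mode) {
  d <- as.numeric(curr) - as.numeric(prev)
  hit <- if (mode == "absolute") abs(d) > tau else d > tau
  matrix(hit, nrow = nrow(curr))
}

#' Bird-pixel segmentation model
#'
#' Bird-representative pixels S(t) are estimated by thresholded deviation
#' from an empty-background reference: `|frame - background| > seg_threshold`,
#' with connected components (4-connectivity) smaller than `min_blob_area`
#' removed as noise specks.
#'
#' @param background Integer matrix: the empty-background reference frame,
#'   typically the per-pixel median of the calibration frames
#'   (see [calibration_model()]).
#' @param seg_threshold Intensity threshold; a natural default is the motion
#'   threshold tau.
#' @param min_blob_area Minimum connected-component area (px) kept.
#' @return An object of class `segmentation_model`.
#' @export
segmentation_model <- function(background, seg_threshold, min_blob_area = 4L) {
  stopifnot(is.matrix(background))
  if (!is_number(seg_threshold) || seg_threshold <= 0) {
    stop("`seg_threshold` must be positive")
  }
  if (!is_count(min_blob_area)) stop("`min_blob_area` must be a count >= 0")
  structure(
    list(background = background, seg_threshold = seg_threshold,
         min_blob_area = as.integer(min_blob_area)),
    class = "segmentation_model"
  )
}

#' Build a segmentation model from a clip's calibration frames
#'
#' Background reference = per-pixel median of the first
#' `cfg$calibration_frames` frames; segmentation threshold defaults to the
#' calibrated motion threshold tau.
#'
#' @param seq A [frame_sequence()] with leading empty-background frames.
#' @param cfg A [threshold_config()].
#' @param seg_threshold Optional override; defaults to
#'   [calibrate_threshold()] on the same frames.
#' @param min_blob_area Minimum blob area kept, in pixels.
#' @return A [segmentation_model()].
#' @export
calibration_model <- function(seq, cfg = threshold_config(),
                              seg_threshold = NULL, min_blob_area = 4L) {
  stopifnot(inherits(seq, "frame_sequence"))
  n <- cfg$calibration_frames
  if (length(seq) < n) {
    stop(sprintf("sequence has %d frame(s) but %d calibration frames required",
                 length(seq), n))
  }
  arr <- simplify2array(seq$frames[seq_len(n)])
  bg <- apply(arr, c(1, 2), stats::median)
  if (is.null(seg_threshold)) seg_threshold <- calibrate_threshold(seq, cfg)
  segmentation_model(bg, seg_threshold, min_blob_area)
}

#' Segment bird-representative pixels
#'
#' @param frame Integer matrix, same dimensions as the model background.
#' @param model A [segmentation_model()].
#' @return A list: `mask` (0/1 integer matrix) and `s` (pixel count,
#'   the S(t) normaliser of the activity index).
#' @export
segment_birds <- function(frame, model) {
  stopifnot(inherits(model, "segmentation_model"))
  if (!is.matrix(frame) || !identical(dim(frame), dim(model$background))) {
    stop("`frame` and model background differ in shape")
  }
  mask <- abs(as.numeric(frame) - as.numeric(model$background)) >
    model$seg_threshold
  mask <- matrix(mask, nrow = nrow(frame))
  if (model$min_blob_area > 1L && any(mask)) {
    lab <- EBImage::bwlabel(mask * 1L)
    sizes <- tabulate(lab)
    if (any(sizes < model$min_blob_area)) {
      keep <- which(sizes >= model$min_blob_area)
      mask <- matrix(lab %in% keep, nrow = nrow(frame))
    }
  }
  storage.mode(mask) <- "integer"
  list(mask = mask, s = sum(mask))
}

#' Activity index of one frame pair
#'
#' AI(t) = (number of changed pixels between t-1 and t) / S(t-1), the count
#' of bird-representative pixels in the previous frame. AI can exceed 1:
#' a bird displaced by more than its own length changes about twice its area.
#' When S(t-1) = 0 the index is undefined and returned as `NA` with a
#' warning, never as a division by zero.
#'
#' @param mask A [motion_mask()] (or 0/1 matrix).
#' @param s_prev Bird-pixel count S(t-1) of the previous frame.
#' @param roi_label,source_id Optional metadata carried into the sample.
#' @param interval Optional sampling interval (seconds); defaults to
#'   `t_curr - t_prev` when the mask carries times.
#' @return A one-row tibble (an activity sample): `source_id`, `roi_label`,
#'   `interval_s`, `t_s`, `changed_pixels`, `bird_pixels`, `ai`.
#' @export
activity_index <- function(mask, s_prev, roi_label = "custom",
                           source_id = "", interval = NULL) {
  if (inherits(mask, "motion_mask")) {
    t_prev <- mask$t_prev
    t_curr <- mask$t_curr
    values <- mask$values
  } else {
    t_prev <- NA_real_
    t_curr <- NA_real_
    values <- mask
  }
  if (!is_count(s_prev)) stop("`s_prev` must be a non-negative count")
  changed <- sum(values != 0)
  if (s_prev > 0) {
    ai <- changed / s_prev
  } else {
    warning("S(t-1) = 0: activity index undefined for this pair")
    ai <- NA_real_
  }
  if (is.null(interval)) interval <- t_curr - t_prev
  tibble::tibble(
    source_id = source_id, roi_label = roi_label,
    interval_s = as.numeric(interval), t_s = as.numeric(t_curr),
    changed_pixels = as.integer(changed), bird_pixels = as.integer(s_prev),
    ai = ai
  )
}

#' Activity-index series over consecutive frame pairs
#'
#' One activity sample per consecutive pair of `seq` (n frames give n - 1
#' samples). For each pair the normaliser S(t-1) is the bird-pixel count
#' segmented in the earlier frame. On a subsampled sequence, "consecutive"
#' means consecutive retained frames, so the per-pair interval equals the
#' subsampling interval.
#'
#' @param seq A [frame_sequence()] of at least 2 frames (a shorter sequence
#'   yields an empty series with a warning).
#' @param model A [segmentation_model()].
#' @param tau Motion threshold; see [calibrate_threshold()].
#' @param mode Differencing mode, `"absolute"` or `"onesided"`.
#' @param roi_label Label carried into the samples.
#' @return A tibble of activity samples (columns as in [activity_index()]).
#'   Pairs with S(t-1) = 0 have `ai = NA`.
#' @export
ai_series <- function(seq, model, tau, mode = c("absolute", "onesided"),
                      roi_label = "custom") {
  stopifnot(inherits(seq, "frame_sequence"),
            inherits(model, "segmentation_model"))
  mode <- match.arg(mode)
  n <- length(seq)
  empty <- tibble::tibble(
    source_id = character(), roi_label = character(),
    interval_s = numeric(), t_s = numeric(),
    changed_pixels = integer(), bird_pixels = integer(), ai = numeric()
  )
  if (n < 2L) {
    warning("sequence has fewer than 2 frames; no pairs to difference")
    return(empty)
  }
  changed <- integer(n - 1L)
  s_prev <- integer(n - 1L)
  for (i in seq_len(n - 1L)) {
    s_prev[i] <- segment_birds(seq$frames[[i]], model)$s
    changed[i] <- sum(diff_exceeds(seq$frames[[i]], seq$frames[[i + 1L]],
                                   tau, mode))
  }
  ai <- ifelse(s_prev > 0, changed / s_prev, NA_real_)
  n_missing <- sum(s_prev == 0)
  if (n_missing > 0) {
    warning(sprintf("%d pair(s) with S(t-1) = 0: ai set to NA", n_missing))
  }
  tibble::tibble(
    source_id = seq$source_id, roi_label = roi_label,
    interval_s = seq$timestamps[-1] - seq$timestamps[-n],
    t_s = seq$timestamps[-1],
    changed_pixels = changed, bird_pixels = s_prev, ai = ai
  )
}

#' Split a clip into calibration frames and analysis frames
#'
#' The first `n` frames (the empty background used for threshold and
#' segmentation calibration) are separated from the remainder, and the
#' analysis part is re-zeroed so its first frame is at t = 0. This keeps
#' window boundaries and long-interval subsampling aligned with the start of
#' the footage under analysis.
#'
#' @param seq A [frame_sequence()].
#' @param n Number of leading calibration frames.
#' @return A list with elements `calibration` and `analysis`, both
#'   [frame_sequence()]s.
#' @export
split_calibration <- function(seq, n = 20L) {
  stopifnot(inherits(seq, "frame_sequence"), is_count(n), n >= 1)
  if (length(seq) <= n) stop("sequence has no frames beyond calibration")
  calib <- seq
  calib$frames <- seq$frames[seq_len(n)]
  calib$timestamps <- seq$timestamps[seq_len(n)]
  rest <- seq
  rest$frames <- seq$frames[-seq_len(n)]
  ts <- seq$timestamps[-seq_len(n)] - seq$timestamps[n + 1L]
  # snap to the frame grid so window boundaries are not perturbed by
  # floating-point residue of the subtraction
  grid <- ts * seq$frame_rate
  if (max(abs(grid - round(grid))) < 1e-6) ts <- round(grid) / seq$frame_rate
  rest$timestamps <- ts
  list(calibration = calib, analysis = rest)
}
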