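#' Temporal subsampling of a frame sequence
#'
#' Keeps frames at indices 0, stride, 2*stride, ... where
#' `stride = interval * frame_rate` must be a whole number of frames.
#' Timestamps are preserved from the source, so downstream windowing sees the
#' true times. The study compares intervals of 0.04 (all frames at 25 fps),
#' 0.2, 1, 10, 60 and 300 s; subsampling from 0.04 s to 0.2 s keeps one frame
#' in five, an 80% reduction in frames to process.
#'
#' @param seq A [frame_sequence()].
#' @param interval Sampling interval in seconds; `interval * frame_rate` must
#'   be a positive integer.
#' @return The subsampled [frame_sequence()].
#' @export
subsample <- function(seq, interval) {
  stopifnot(inherits(seq, "frame_sequence"))
  if (!is_number(interval) || interval <= 0) {
    stop("`interval` must be a positive number of seconds")
  }
  stride <- interval * seq$frame_rate
  if (abs(stride - round(stride)) > 1e-9 || round(stride) < 1) {
    stop(sprintf(
      "interval %g s at %g fps gives non-integer frame stride %g",
      interval, seq$frame_rate, stride
    ))
  }
  stride <- as.integer(round(stride))
  if (stride == 1L) return(seq)
  idx <- seq.int(1L, length(seq), by = stride)
  out <- seq
  out$frames <- seq$frames[idx]
  out$timestamps <- seq$timestamps[idx]
  out
}

#' The study's sampling-interval set
#'
#' @return `c(0.04, 0.2, 1, 10, 60, 300)` seconds.
#' @export
study_intervals <- function() c(0.04, 0.2, 1, 10, 60, 300)

#' Cumulative activity over fixed time windows
#'
#' Sums activity samples within consecutive windows of `window` seconds
#' (study value 300). A sample belongs to the window containing its
#' current-frame time, with half-open bounds `[start, end)`. Only complete
#' windows — `floor(clip_duration / window)` of them — are emitted; a
#' trailing partial window is dropped (a 56-min clip yields 11 complete
#' 300-s windows). Samples with missing `ai` (undefined S(t-1)) are skipped
#' and counted in `n_missing`. A complete window containing no sample (as
#' happens at sampling intervals comparable to the window length) is emitted
#' with `n_samples = 0` and `cumulative_ai = 0`.
#'
#' @param samples A tibble of activity samples (see [ai_series()]).
#' @param window Window length in seconds.
#' @param clip_duration Total analysed clip duration in seconds.
#' @return A tibble of cumulative windows: `source_id`, `roi_label`,
#'   `interval_s`, `window_start`, `window_end`, `cumulative_ai`,
#'   `n_samples`, `n_missing`.
#' @export
cumulative_windows <- function(samples, window = 300, clip_duration) {
  if (!is_number(window) || window <= 0) stop("`window` must be positive")
  if (!is_number(clip_duration) || clip_duration <= 0) {
    stop("`clip_duration` must be positive")
  }
  n_win <- floor(clip_duration / window)
  if (n_win < 1) stop("clip shorter than one window")
  starts <- (seq_len(n_win) - 1) * window
  meta <- function(col, default) {
    if (nrow(samples) > 0) samples[[col]][1] else default
  }
  idx <- findInterval(samples$t_s, c(starts, n_win * window),
                      rightmost.closed = FALSE, left.open = FALSE)
  in_win <- idx >= 1 & idx <= n_win & samples$t_s < n_win * window
  cum <- n_val <- n_na <- numeric(n_win)
  for (w in seq_len(n_win)) {
    ai <- samples$ai[in_win & idx == w]
    cum[w] <- sum(ai, na.rm = TRUE)
    n_val[w] <- sum(!is.na(ai))
    n_na[w] <- sum(is.na(ai))
  }
  tibble::tibble(
    source_id = meta("source_id", ""),
    roi_label = meta("roi_label", "custom"),
    interval_s = meta("interval_s", NA_real_),
    window_start = starts,
    window_end = starts + window,
    cumulative_ai = cum,
    n_samples = as.integer(n_val),
    n_missing = as.integer(n_na)
  )
}

#' Compare sampling intervals against the full-frame baseline
#'
#' Windows computed at several sampling intervals from the same footage are
#' paired by (`source_id`, `roi_label`, `window_start`) with the windows at
#' the baseline interval (0.04 s, i.e. every frame at 25 fps). Per window,
#' the ratio is `100 * cumulative_ai(interval) / cumulative_ai(baseline)`;
#' per interval the table reports the mean of those per-window ratios
#' (`ratio_pct`, the primary statistic), the ratio of mean cumulative AI
#' (`ratio_of_means_pct`), and mean cumulative AI with its standard error.
#' Windows whose baseline cumulative AI is 0 are excluded from ratios and
#' counted in `n_zero_baseline`.
#'
#' @param windows A tibble of cumulative windows (rows for all intervals,
#'   see [cumulative_windows()]); every interval must cover the same set of
#'   (`source_id`, `roi_label`, `window_start`) keys.
#' @param baseline Baseline interval in seconds.
#' @return A tibble with one row per interval: `interval_s`, `n_windows`,
#'   `mean_cumulative_ai`, `sem`, `ratio_pct`, `ratio_of_means_pct`,
#'   `n_zero_baseline`.
#' @export
ratio_to_baseline <- function(windows, baseline = 0.04) {
  stopifnot(is.data.frame(windows))
  ints <- sort(unique(windows$interval_s))
  if (!any(abs(ints - baseline) < 1e-12)) {
    stop(sprintf("baseline interval %g s absent from `windows`", baseline))
  }
  base <- windows[abs(windows$interval_s - baseline) < 1e-12, ]
  key <- function(d) paste(d$source_id, d$roi_label, d$window_start, sep = "\r")
  base_ai <- stats::setNames(base$cumulative_ai, key(base))
  if (anyDuplicated(names(base_ai))) {
    stop("duplicate baseline windows for the same source/roi/window_start")
  }
  out <- lapply(ints, function(iv) {
    w <- windows[abs(windows$interval_s - iv) < 1e-12, ]
    b <- base_ai[key(w)]
    if (anyNA(b)) stop("window boundaries differ between intervals")
    ok <- b > 0
    if (any(!ok)) {
      message(sprintf("interval %g s: %d window(s) with zero baseline AI excluded from ratios",
                      iv, sum(!ok)))
    }
    ratios <- 100 * w$cumulative_ai[ok] / b[ok]
    m <- mean(w$cumulative_ai)
    sem <- if (nrow(w) > 1) stats::sd(w$cumulative_ai) / sqrt(nrow(w)) else NA_real_
    tibble::tibble(
      interval_s = iv,
      n_windows = nrow(w),
      mean_cumulative_ai = m,
      sem = sem,
      ratio_pct = if (length(ratios) > 0) mean(ratios) else NA_real_,
      ratio_of_means_pct = 100 * m / mean(base$cumulative_ai),
      n_zero_baseline = sum(!ok)
    )
  })
  dplyr::bind_rows(out)
}

#' Grouped mean and SEM of cumulative activity
#'
#' The computational skeleton of the study's summary tables: per group, the
#' number of windows, mean cumulative AI and the plain standard error of the
#' mean (sd / sqrt(n); undefined for a single window).
#'
#' @param windows A tibble of cumulative windows, carrying any grouping
#'   metadata columns (e.g. `age_week`, `roi_label`, `time_of_day`,
#'   `interval_s`).
#' @param keys Character vector of grouping column names (non-empty).
#' @return A tibble with the key columns plus `n`, `mean_cumulative_ai`,
#'   `sem`.
#' @export
summarize_groups <- function(windows, keys) {
  stopifnot(is.data.frame(windows))
  if (length(keys) == 0) stop("`keys` must name at least one grouping column")
  missing_keys <- setdiff(keys, names(windows))
  if (length(missing_keys) > 0) {
    stop("grouping column(s) absent: ", paste(missing_keys, collapse = ", "))
  }
  windows |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_cumulative_ai = mean(.data$cumulative_ai),
      sem = ifelse(dplyr::n() > 1,
                   stats::sd(.data$cumulative_ai) / sqrt(dplyr::n()),
                   NA_real_),
      .groups = "drop"
    )
}
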