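# synthetic activity-sample tibble on the 0.04-s grid
make_samples <- function(n, ai, fps = 25, interval = 1 / fps,
                         source_id = "clip", roi_label = "open") {
  stride <- interval * fps
  tibble::tibble(
    source_id = source_id, roi_label = roi_label,
    interval_s = interval, t_s = (seq_len(n) * stride) / fps,
    changed_pixels = NA_integer_, bird_pixels = NA_integer_,
    ai = rep_len(ai, n)
  )
}

test_that("subsampling keeps every stride-th frame with timestamps intact", {
  s <- rand_seq(50, h = 2, w = 2, seed = 4)
  sub <- subsample(s, 0.2)                     # stride 5 at 25 fps
  expect_equal(length(sub), 10L)
  expect_identical(sub$frames[[2]], s$frames[[6]])
  expect_equal(sub$timestamps, s$timestamps[seq(1, 50, by = 5)])
  # the full-frame interval is the identity
  expect_identical(subsample(s, 0.04)$frames, s$frames)
  expect_error(subsample(s, 0.3), "stride 7.5")
  expect_error(subsample(s, -1), "positive")
})

test_that("subsampling composes multiplicatively in the stride", {
  s <- rand_seq(300, h = 2, w = 2, seed = 8)
  # strides 5 then 25 on the retained frames = stride 125 on the source
  twice <- subsample(subsample(s, 0.2), 1)
  once <- subsample(s, 0.2 * 1 * 25)
  expect_identical(twice$frames, once$frames)
  expect_equal(twice$timestamps, once$timestamps)
})

test_that("ai on a subsampled sequence equals ai over retained pairs", {
  s <- rand_seq(40, h = 8, w = 8, seed = 12)
  model <- segmentation_model(int_matrix(0L, 8, 8), 30, 1)
  sub <- subsample(s, 0.2)
  got <- ai_series(sub, model, tau = 25)
  idx <- seq(1, 40, by = 5)
  manual <- vapply(seq_len(length(idx) - 1L), function(k) {
    prev <- s$frames[[idx[k]]]
    curr <- s$frames[[idx[k + 1L]]]
    sum(motion_mask(prev, curr, 25)$values) / segment_birds(prev, model)$s
  }, numeric(1))
  expect_equal(got$ai, manual)
  expect_equal(got$interval_s, rep(0.2, length(manual)))
})

test_that("a 56-min clip yields 11 complete 300-s windows, 3600 s yields 12", {
  samples <- make_samples(56 * 60 * 25, ai = 0.01)
  w56 <- cumulative_windows(samples, window = 300, clip_duration = 56 * 60)
  expect_equal(nrow(w56), 11L)
  w60 <- cumulative_windows(make_samples(3600 * 25, ai = 0.002),
                            window = 300, clip_duration = 3600)
  expect_equal(nrow(w60), 12L)
  expect_error(cumulative_windows(samples, window = 0, clip_duration = 100),
               "positive")
  expect_error(cumulative_windows(samples, window = 300, clip_duration = 100),
               "shorter than one window")
})

test_that("window sums match a direct summation oracle", {
  samples <- make_samples(22500, ai = 0.01)       # 900 s of constant ai
  w <- cumulative_windows(samples, 300, 900)
  # direct per-window recomputation
  oracle <- vapply(w$window_start, function(st) {
    sum(samples$ai[samples$t_s >= st & samples$t_s < st + 300])
  }, numeric(1))
  expect_equal(w$cumulative_ai, oracle)
  # an interior window holds exactly 300 s x 25 fps samples of 0.01 each
  expect_equal(w$cumulative_ai[2], 0.01 * 7500)
  expect_equal(w$n_samples[2], 7500L)
  expect_true(all(w$n_samples <= 300 * 25))
})

test_that("missing samples are skipped and counted per window", {
  samples <- make_samples(15000, ai = 0.01)
  samples$ai[c(10, 20, 8000)] <- NA
  w <- cumulative_windows(samples, 300, 600)
  expect_equal(w$n_missing, c(2L, 1L))
  # partition over covered time: the sample at exactly t = 600 s falls on
  # the open end of the last window and is outside the covered span
  expect_equal(sum(w$n_samples) + sum(w$n_missing), 14999L)
  expect_equal(w$cumulative_ai[1], 0.01 * (7499 - 2))
})

test_that("ratios to baseline are per-window, averaged per interval", {
  base <- make_samples(15000, ai = 0.01)
  w_base <- cumulative_windows(base, 300, 600)
  # identical series: ratio 100%
  both <- dplyr::bind_rows(w_base, within(w_base, interval_s <- 0.2))
  cmp <- ratio_to_baseline(both, baseline = 0.04)
  expect_equal(cmp$ratio_pct, c(100, 100))
  # exactly halved cumulative AI: ratio 50%
  halved <- within(w_base, {interval_s <- 1; cumulative_ai <- cumulative_ai / 2})
  cmp2 <- ratio_to_baseline(dplyr::bind_rows(w_base, halved), 0.04)
  expect_equal(cmp2$ratio_pct[cmp2$interval_s == 1], 50)
  expect_error(ratio_to_baseline(w_base, baseline = 0.2), "absent")
})

test_that("mean ratio matches brute-force per-window recomputation", {
  set.seed(31)
  w <- list()
  for (iv in c(0.04, 1, 10)) {
    wi <- cumulative_windows(make_samples(15000, ai = 0.01), 300, 600)
    wi$interval_s <- iv
    wi$cumulative_ai <- stats::runif(nrow(wi), 0, 50)
    w[[as.character(iv)]] <- wi
  }
  windows <- dplyr::bind_rows(w)
  cmp <- ratio_to_baseline(windows, 0.04)
  for (iv in c(1, 10)) {
    ratios <- 100 * w[[as.character(iv)]]$cumulative_ai /
      w[["0.04"]]$cumulative_ai
    expect_equal(cmp$ratio_pct[cmp$interval_s == iv], mean(ratios))
    expect_equal(cmp$ratio_of_means_pct[cmp$interval_s == iv],
                 100 * mean(w[[as.character(iv)]]$cumulative_ai) /
                   mean(w[["0.04"]]$cumulative_ai))
  }
})

test_that("zero-baseline windows are excluded from ratios and counted", {
  w_base <- cumulative_windows(make_samples(15000, ai = 0.01), 300, 600)
  w_base$cumulative_ai[1] <- 0
  other <- within(w_base, {interval_s <- 1; cumulative_ai <- c(5, 10)})
  expect_message(cmp <- ratio_to_baseline(dplyr::bind_rows(w_base, other), 0.04),
                 "zero baseline")
  expect_equal(cmp$n_zero_baseline, c(1L, 1L))
  expect_equal(cmp$ratio_pct[2], 100 * 10 / w_base$cumulative_ai[2])
})

test_that("group summaries report n, mean and plain SEM", {
  w <- tibble::tibble(
    roi_label = c("open", "open", "feeder"),
    age_week = c(1L, 1L, 1L),
    cumulative_ai = c(10, 20, 7)
  )
  s <- summarize_groups(w, "roi_label")
  open <- s[s$roi_label == "open", ]
  expect_equal(open$mean_cumulative_ai, 15)
  expect_equal(open$sem, 5)           # sd(c(10,20))/sqrt(2)
  expect_true(is.na(s$sem[s$roi_label == "feeder"]))
  expect_equal(sum(s$n), nrow(w))     # groups partition the windows
  expect_error(summarize_groups(w, character(0)), "at least one")
  expect_error(summarize_groups(w, "time_of_day"), "absent")
})
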