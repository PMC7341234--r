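test_that("threshold calibration takes a fraction of the calibration maximum", {
  s <- const_seq(20, value = 200L)
  expect_equal(calibrate_threshold(s, threshold_config(0.15, 20)), 30)
  s255 <- const_seq(20, value = 255L)
  expect_equal(calibrate_threshold(s255, threshold_config(0.15, 20)), 38.25)
  expect_error(calibrate_threshold(const_seq(5), threshold_config(0.15, 20)),
               "5 frame")
  expect_error(calibrate_threshold(const_seq(20, value = 0L),
                                   threshold_config()),
               "degenerate calibration")
  # whole-clip maximum by flag
  s <- const_seq(21, value = 10L)
  s$frames[[21]][1, 1] <- 100L
  expect_equal(calibrate_threshold(s, threshold_config(0.15, 20)), 1.5)
  expect_equal(calibrate_threshold(s, threshold_config(0.15, 20),
                                   use_all_frames = TRUE), 15)
})

test_that("motion masks follow the thresholded difference, strict and signed", {
  prev <- int_matrix(100L, 3, 3)
  curr <- int_matrix(120L, 3, 3)
  expect_true(all(motion_mask(prev, curr, 15, "onesided")$values == 1L))
  # the one-sided rule misses darkening pixels; absolute catches them
  expect_true(all(motion_mask(curr, prev, 15, "onesided")$values == 0L))
  expect_true(all(motion_mask(curr, prev, 15, "absolute")$values == 1L))
  # identical frames give an all-zero mask for any positive threshold
  expect_true(all(motion_mask(prev, prev, 0.5)$values == 0L))
  # strict inequality: a difference exactly at tau does not fire
  expect_true(all(motion_mask(prev, int_matrix(115L, 3, 3), 15)$values == 0L))
  expect_error(motion_mask(prev, int_matrix(0L, 2, 3), 15), "identical dim")
})

test_that("segmentation counts background-deviating pixels above min blob area", {
  bg <- int_matrix(50L, 20, 20)
  model <- segmentation_model(bg, seg_threshold = 60, min_blob_area = 4)
  expect_equal(segment_birds(bg, model)$s, 0L)
  one_block <- block_frame(bg = 50L, block = 200L, rows = 3:12, cols = 5:14)
  expect_equal(segment_birds(one_block, model)$s, 100L)
  # a 2-px speck is removed by the blob-area floor
  speck <- one_block
  speck[18, 18:19] <- 200L
  seg <- segment_birds(speck, model)
  expect_equal(seg$s, 100L)
  expect_equal(seg$s,
               oracle_segment_count(speck, bg, 60, 4))
  expect_error(segment_birds(int_matrix(0L, 5, 5), model), "shape")
})

test_that("blob filtering agrees with a flood-fill oracle on random masks", {
  bg <- int_matrix(0L, 12, 12)
  for (seed in 1:25) {
    set.seed(seed)
    frame <- int_matrix(sample(c(0L, 100L), 144, replace = TRUE,
                               prob = c(0.7, 0.3)), 12, 12)
    for (min_area in c(1L, 3L, 6L)) {
      model <- segmentation_model(bg, 50, min_area)
      expect_equal(segment_birds(frame, model)$s,
                   oracle_segment_count(frame, bg, 50, min_area),
                   info = sprintf("seed %d, min_area %d", seed, min_area))
    }
  }
})

test_that("the activity index is changed pixels over previous bird pixels", {
  mask <- int_matrix(0L, 2, 2)
  mask[1, 1:2] <- 1L
  expect_equal(activity_index(mask, 4)$ai, 0.5)
  expect_equal(activity_index(int_matrix(0L, 10, 10), 100)$ai, 0)
  # ai may exceed 1: a fast bird changes about twice its own area
  expect_equal(activity_index(int_matrix(1L, 10, 15), 100)$ai, 1.5)
  expect_warning(res <- activity_index(mask, 0), "S\\(t-1\\) = 0")
  expect_true(is.na(res$ai))
})

test_that("ai_series yields one sample per consecutive pair", {
  # static scene with a bright block: S > 0, nothing changes, ai = 0
  f <- block_frame(bg = 20L, block = 220L)
  s <- frame_sequence(list(f, f, f), 25)
  model <- segmentation_model(int_matrix(20L, 20, 20), 60, 4)
  out <- ai_series(s, model, tau = 15)
  expect_equal(nrow(out), 2L)
  expect_equal(out$ai, c(0, 0))
  expect_equal(out$bird_pixels, c(100L, 100L))
  expect_equal(out$t_s, c(0.04, 0.08))
  # n frames -> n - 1 samples
  s8 <- rand_seq(8, seed = 5)
  out8 <- ai_series(s8, segmentation_model(int_matrix(0L, 8, 8), 10, 1), 20)
  expect_equal(nrow(out8), 7L)
  expect_warning(empty <- ai_series(const_seq(1), model, 15), "fewer than 2")
  expect_equal(nrow(empty), 0L)
})

test_that("vectorized pipeline matches the nested-loop oracle bit-exactly", {
  for (seed in 1:20) {
    s <- rand_seq(3, h = 8, w = 8, seed = seed)
    set.seed(seed + 1000)
    bg <- int_matrix(sample.int(256, 64, replace = TRUE) - 1L, 8, 8)
    mode <- if (seed %% 2 == 0) "absolute" else "onesided"
    model <- segmentation_model(bg, seg_threshold = 40, min_blob_area = 1)
    got <- ai_series(s, model, tau = 25, mode = mode)$ai
    want <- oracle_ai_series(s, bg, 40, 25, mode)
    expect_identical(got, want, info = paste("seed", seed, mode))
  }
})

test_that("changed-pixel counts are non-increasing in the threshold", {
  s <- rand_seq(2, h = 16, w = 16, seed = 9)
  counts <- vapply(c(0.5, 5, 15, 40, 100, 254),
                   function(tau) sum(motion_mask(s$frames[[1]], s$frames[[2]],
                                                 tau)$values),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("full-pixel replacement saturates at the frame area", {
  prev <- int_matrix(10L, 6, 7)
  curr <- int_matrix(200L, 6, 7)
  m <- motion_mask(prev, curr, 15)
  expect_equal(sum(m$values), 42L)
})

test_that("splitting calibration frames rebases analysis time to zero", {
  s <- rand_seq(30, seed = 2)
  parts <- split_calibration(s, 20)
  expect_equal(length(parts$calibration), 20L)
  expect_equal(length(parts$analysis), 10L)
  expect_equal(parts$analysis$timestamps[1], 0)
  expect_equal(parts$analysis$timestamps, (0:9) / 25)
  expect_error(split_calibration(rand_seq(10, seed = 1), 20), "no frames beyond")
})
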