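# fixture builders and independent brute-force oracles

int_matrix <- function(x, nrow, ncol) {
  m <- matrix(as.integer(x), nrow, ncol)
  m
}

# n identical frames of a constant value
const_seq <- function(n, value = 0L, h = 10L, w = 10L, fps = 25) {
  frame_sequence(replicate(n, int_matrix(value, h, w), simplify = FALSE),
                 frame_rate = fps)
}

# n frames of seeded uniform integer noise
rand_seq <- function(n, h = 8L, w = 8L, fps = 25, max_int = 255L, seed = 1L) {
  set.seed(seed)
  frames <- replicate(n, int_matrix(sample.int(max_int + 1L, h * w,
                                               replace = TRUE) - 1L, h, w),
                      simplify = FALSE)
  frame_sequence(frames, frame_rate = fps, max_intensity = max_int)
}

# a frame with a constant background and one bright rectangular block
block_frame <- function(h = 20L, w = 20L, bg = 0L, block = 200L,
                        rows = 1:10, cols = 1:10) {
  m <- int_matrix(bg, h, w)
  m[rows, cols] <- as.integer(block)
  m
}

# brute-force 4-connected component labelling by flood fill
oracle_label <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  for (r in seq_len(nrow(mask))) {
    for (c in seq_len(ncol(mask))) {
      if (mask[r, c] && lab[r, c] == 0L) {
        nxt <- nxt + 1L
        stack <- list(c(r, c))
        while (length(stack) > 0) {
          p <- stack[[length(stack)]]
          stack[[length(stack)]] <- NULL
          if (p[1] < 1 || p[1] > nrow(mask) || p[2] < 1 || p[2] > ncol(mask)) next
          if (!mask[p[1], p[2]] || lab[p[1], p[2]] != 0L) next
          lab[p[1], p[2]] <- nxt
          stack <- c(stack, list(c(p[1] - 1L, p[2])), list(c(p[1] + 1L, p[2])),
                     list(c(p[1], p[2] - 1L)), list(c(p[1], p[2] + 1L)))
        }
      }
    }
  }
  lab
}

# brute-force segmentation pixel count with small-blob removal
oracle_segment_count <- function(frame, background, seg_threshold,
                                 min_blob_area) {
  mask <- abs(frame - background) > seg_threshold
  lab <- oracle_label(mask)
  sizes <- tabulate(lab)
  sum(sizes[sizes >= min_blob_area])
}

# nested per-pixel loop over Eq-style thresholded differencing and
# background-deviation segmentation; the independent oracle for ai_series
oracle_ai_series <- function(seq, background, seg_threshold, tau, mode) {
  n <- length(seq$frames)
  h <- nrow(background)
  w <- ncol(background)
  ai <- numeric(n - 1L)
  for (i in seq_len(n - 1L)) {
    prev <- seq$frames[[i]]
    curr <- seq$frames[[i + 1L]]
    s <- 0L
    changed <- 0L
    for (r in seq_len(h)) {
      for (c in seq_len(w)) {
        if (abs(prev[r, c] - background[r, c]) > seg_threshold) s <- s + 1L
        d <- curr[r, c] - prev[r, c]
        hit <- if (mode == "absolute") abs(d) > tau else d > tau
        if (hit) changed <- changed + 1L
      }
    }
    ai[i] <- if (s > 0L) changed / s else NA_real_
  }
  ai
}
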