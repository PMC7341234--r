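#' Frame sequences
#'
#' A `frame_sequence` is an ordered set of grayscale frames sampled at a fixed
#' frame rate. Frames are integer matrices indexed `[row, column]` (row = y,
#' column = x), all of identical size, with intensities in
#' `[0, max_intensity]`. Timestamps are seconds from the start of the
#' sequence; for a full-frame sequence they are `index / frame_rate`.
#'
#' @param frames List of integer matrices of identical dimensions.
#' @param frame_rate Frames per second of the source video (e.g. 25).
#' @param timestamps Optional numeric vector of per-frame times in seconds,
#'   strictly increasing. Defaults to `(seq_along(frames) - 1) / frame_rate`.
#' @param source_id Free-text label for the clip (location, age, seed, ...).
#' @param max_intensity Maximum representable intensity (255 for 8-bit).
#' @return An object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, frame_rate, timestamps = NULL,
                           source_id = "", max_intensity = 255L) {
  if (!is.list(frames)) stop("`frames` must be a list of matrices")
  if (!is_number(frame_rate) || frame_rate <= 0) {
    stop("`frame_rate` must be a positive number")
  }
  if (length(frames) == 0L) stop("no frames")
  dims <- vapply(frames, function(f) {
    if (!is.matrix(f)) stop("each frame must be a matrix")
    dim(f)
  }, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("inconsistent geometry: frames differ in height or width")
  }
  rng <- range(vapply(frames, function(f) range(f), numeric(2)))
  if (rng[1] < 0 || rng[2] > max_intensity) {
    stop("intensities outside [0, max_intensity]")
  }
  if (is.null(timestamps)) {
    timestamps <- (seq_along(frames) - 1) / frame_rate
  }
  if (length(timestamps) != length(frames)) {
    stop("`timestamps` must have one entry per frame")
  }
  if (length(timestamps) > 1L && any(diff(timestamps) <= 0)) {
    stop("`timestamps` must be strictly increasing")
  }
  structure(
    list(
      frames = frames,
      frame_rate = frame_rate,
      timestamps = as.numeric(timestamps),
      source_id = source_id,
      max_intensity = max_intensity
    ),
    class = "frame_sequence"
  )
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

#' @export
dim.frame_sequence <- function(x) dim(x$frames[[1]])

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<frame_sequence> %d frame(s), %dx%d px, %g fps, %.2f-%.2f s%s\n",
    length(x), d[1], d[2], x$frame_rate,
    x$timestamps[1], x$timestamps[length(x)],
    if (nzchar(x$source_id)) paste0(" [", x$source_id, "]") else ""
  ))
  invisible(x)
}

#' Convert an image array to integer grayscale
#'
#' RGB arrays are reduced with ITU-R BT.601 luma weights
#' (0.299 R + 0.587 G + 0.114 B) and rounded half-up to integers, so the
#' conversion is deterministic across platforms. Grayscale input is returned
#' unchanged (identity on already-integer matrices).
#'
#' @param img A matrix (grayscale) or `h x w x 3` array (RGB), either on the
#'   integer intensity scale or normalised to `[0, 1]`.
#' @param max_intensity Intensity ceiling of the target integer scale.
#' @param normalized Set `TRUE` when `img` is on `[0, 1]` (as returned by
#'   [png::readPNG()]); intensities are rescaled by `max_intensity` first.
#' @return An integer matrix.
#' @export
to_grayscale <- function(img, max_intensity = 255L, normalized = FALSE) {
  d <- dim(img)
  if (length(d) == 3L) {
    img <- if (d[3] < 3L) {
      img[, , 1, drop = FALSE]
    } else {
      0.299 * img[, , 1, drop = FALSE] + 0.587 * img[, , 2, drop = FALSE] +
        0.114 * img[, , 3, drop = FALSE]
    }
  }
  if (normalized) img <- img * max_intensity
  m <- matrix(round_half_up(img), nrow = d[1], ncol = d[2])
  m <- clip(m, 0, as.integer(max_intensity))
  storage.mode(m) <- "integer"
  m
}

read_frame_file <- function(path, max_intensity) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported frame format: ", ext)
  )
  to_grayscale(img, max_intensity = max_intensity, normalized = TRUE)
}

#' Load a frame sequence from a directory of image files
#'
#' Files are taken in byte-wise lexicographic order (C locale), which is
#' defined to be temporal order; timestamps are computed as
#' `index / frame_rate`, never read from file metadata, so a reload is always
#' reproducible. Color frames are converted to grayscale via [to_grayscale()].
#' Video containers must be decoded to frames upstream (e.g. with ffmpeg);
#' a non-directory path is an error.
#'
#' @param path Directory containing PNG or TIFF frames.
#' @param frame_rate Frames per second the frames were extracted at.
#' @param max_intensity Intensity ceiling of the stored frames (255 = 8-bit).
#' @param pattern Regular expression selecting frame files.
#' @param source_id Label for the sequence; defaults to the directory name.
#' @param remap Optional per-frame remapping hook, a
#'   `function(matrix) -> matrix`, applied to each grayscale frame before
#'   assembly. Intended for user-supplied lens-distortion correction; the
#'   package ships no lens model.
#' @return A [frame_sequence()].
#' @export
load_sequence <- function(path, frame_rate, max_intensity = 255L,
                          pattern = "\\.(png|tif|tiff)$",
                          source_id = basename(path), remap = NULL) {
  if (!dir.exists(path)) {
    stop(
      "`path` must be a directory of frames; decode video files to ",
      "PNG/TIFF frames upstream: ", path
    )
  }
  files <- list.files(path, pattern = pattern, full.names = TRUE,
                      ignore.case = TRUE)
  files <- files[order(basename(files), method = "radix")]
  if (length(files) == 0L) stop("no frames in ", path)
  frames <- lapply(files, read_frame_file, max_intensity = max_intensity)
  if (!is.null(remap)) {
    stopifnot(is.function(remap))
    frames <- lapply(frames, remap)
  }
  frame_sequence(frames, frame_rate = frame_rate,
                 source_id = source_id, max_intensity = max_intensity)
}

#' Write a frame sequence to numbered PNG files
#'
#' Lossless 8/16-bit PNG output; [load_sequence()] on the written directory
#' reproduces intensities bit-exactly.
#'
#' @param seq A [frame_sequence()].
#' @param dir Output directory (created if absent).
#' @param prefix Filename prefix; files are `prefix_000001.png`, ...
#' @return Invisibly, the written file paths.
#' @export
write_frames <- function(seq, dir, prefix = "frame") {
  stopifnot(inherits(seq, "frame_sequence"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, sprintf("%s_%06d.png", prefix, seq_along(seq$frames)))
  for (i in seq_along(seq$frames)) {
    png::writePNG(seq$frames[[i]] / seq$max_intensity, paths[i])
  }
  invisible(paths)
}

#' Write a binary mask as a 0/255 PNG
#'
#' @param mask A binary (0/1 or logical) matrix, or a [motion_mask()].
#' @param path Output PNG path.
#' @return Invisibly, `path`.
#' @export
write_mask <- function(mask, path) {
  if (inherits(mask, "motion_mask")) mask <- mask$values
  png::writePNG((mask != 0) * 1, path)
  invisible(path)
}

#' Rectangular region of interest
#'
#' Coordinates are 0-based with half-open extents: the ROI covers columns
#' `[x0, x0 + width)` and rows `[y0, y0 + height)` of the frame. The study
#' regions are 200 x 200 px squares at the feeder, drinker and open area.
#'
#' @param x0,y0 Top-left pixel (0-based, inclusive).
#' @param width,height Extent in pixels.
#' @param label One of `"feeder"`, `"drinker"`, `"open"`, `"custom"`.
#' @return An object of class `roi`.
#' @export
roi <- function(x0, y0, width = 200L, height = 200L, label = "custom") {
  stopifnot(is_count(x0), is_count(y0))
  if (!is_count(width) || width < 1 || !is_count(height) || height < 1) {
    stop("`width` and `height` must be positive integers")
  }
  label <- match.arg(label, c("feeder", "drinker", "open", "custom"))
  structure(
    list(x0 = as.integer(x0), y0 = as.integer(y0),
         width = as.integer(width), height = as.integer(height),
         label = label),
    class = "roi"
  )
}

#' Crop every frame of a sequence to an ROI
#'
#' Timestamps, frame rate and metadata are unchanged; cropping twice with the
#' same full-extent ROI is the identity.
#'
#' @param seq A [frame_sequence()].
#' @param region An [roi()].
#' @return The cropped [frame_sequence()].
#' @export
crop <- function(seq, region) {
  stopifnot(inherits(seq, "frame_sequence"), inherits(region, "roi"))
  d <- dim(seq)
  if (region$x0 + region$width > d[2] || region$y0 + region$height > d[1]) {
    stop(sprintf(
      "roi out of bounds: extends to (x=%d, y=%d) but frames are %dx%d (w x h)",
      region$x0 + region$width, region$y0 + region$height, d[2], d[1]
    ))
  }
  rows <- (region$y0 + 1L):(region$y0 + region$height)
  cols <- (region$x0 + 1L):(region$x0 + region$width)
  out <- seq
  out$frames <- lapply(seq$frames, function(f) f[rows, cols, drop = FALSE])
  out
}

#' Physical scale of a square ROI
#'
#' The study's 200-px ROI spans 0.71 m, giving 0.00355 m per pixel.
#'
#' @param region An [roi()]; must be square when a single `physical_side`
#'   is given.
#' @param physical_side Side length of the region in meters.
#' @return Meters per pixel.
#' @export
pixel_scale <- function(region, physical_side) {
  stopifnot(inherits(region, "roi"))
  if (!is_number(physical_side) || physical_side <= 0) {
    stop("`physical_side` must be a positive length in meters")
  }
  if (region$width != region$height) {
    stop("roi is not square; a single `physical_side` is ambiguous")
  }
  physical_side / region$width
}
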