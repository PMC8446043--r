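#' Calibrated image sequence
#'
#' The common container of all pipelines: a time-lapse stack with physical
#' calibration.  Frames are stored as a 3-D numeric array indexed
#' `(time, row, col)`; pixel coordinates are 0-based and pixel-centered, so a
#' pixel index `i` sits at physical position `i * pixel_size_um` micrometres.
#'
#' @param frames 3-D numeric array `(time, row, col)` of non-negative
#'   intensities, or a list of equally shaped matrices.
#' @param pixel_size_um Physical pixel size in micrometres per pixel (> 0).
#' @param frame_interval_s Time between consecutive frames in seconds (> 0);
#'   the elementary delay of the DDM lag grid.
#' @param t0_index 1-based index of the first post-event frame (first
#'   post-bleach frame for FRAP/FLIP, 1 for plain acquisitions).
#' @return An object of class `ImageSequence`.
#' @export
image_sequence <- function(frames, pixel_size_um, frame_interval_s,
                           t0_index = 1L) {
  if (is.list(frames)) {
    shapes <- vapply(frames, dim, integer(2))
    if (any(shapes != shapes[, 1])) stop("all frames must share one shape")
    arr <- array(0, c(length(frames), nrow(frames[[1]]), ncol(frames[[1]])))
    for (i in seq_along(frames)) arr[i, , ] <- frames[[i]]
    frames <- arr
  }
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("frames must be a (time, row, col) array or list of matrices")
  if (dim(frames)[1] < 2L) stop("an ImageSequence needs at least 2 frames")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      pixel_size_um <= 0) stop("pixel_size_um must be a single positive number")
  if (!is.numeric(frame_interval_s) || length(frame_interval_s) != 1L ||
      frame_interval_s <= 0) stop("frame_interval_s must be a single positive number")
  t0_index <- as.integer(t0_index)
  if (t0_index < 1L || t0_index > dim(frames)[1])
    stop("t0_index out of range")
  structure(list(frames = frames,
                 pixel_size_um = as.numeric(pixel_size_um),
                 frame_interval_s = as.numeric(frame_interval_s),
                 t0_index = t0_index),
            class = "ImageSequence")
}

#' @export
print.ImageSequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "ImageSequence: %d frames of %d x %d px (%.3g um/px, %.4g s/frame, t0 = %d)\n",
    d[1], d[2], d[3], x$pixel_size_um, x$frame_interval_s, x$t0_index))
  invisible(x)
}

#' @export
dim.ImageSequence <- function(x) dim(x$frames)

n_frames <- function(seq) dim(seq$frames)[1]

#' Read an image sequence from a grayscale TIFF stack
#'
#' Pages are taken in file order as time points and cast to floating point.
#'
#' @inheritParams image_sequence
#' @param path Path to a single- or multi-page grayscale TIFF.
#' @return An [image_sequence()].
#' @export
read_image_sequence <- function(path, pixel_size_um, frame_interval_s,
                                t0_index = 1L) {
  tf <- read_tiff(path)
  if (length(tf$pages) < 2L)
    stop("TIFF stack has fewer than 2 pages; not a time-lapse: ", path)
  image_sequence(tf$pages, pixel_size_um, frame_interval_s, t0_index)
}

#' Write an image sequence to a multi-page TIFF
#'
#' @param seq An [image_sequence()].
#' @param path Output path.
#' @param bits Sample depth: 8 or 16 (unsigned integer; intensities must fit)
#'   or 32 (float, default — lossless for simulator output).
#' @return `path`, invisibly.
#' @export
write_image_sequence <- function(seq, path, bits = 32) {
  stopifnot(inherits(seq, "ImageSequence"))
  write_tiff(seq$frames, path, bits = bits)
}
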