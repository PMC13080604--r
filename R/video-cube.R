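#' Video cube container
#'
#' A `video_cube` is a T x H x W array of non-negative pixel intensities with
#' a frame rate, the raw material of vibration imaging. Frame `t` is the
#' H x W matrix `v[t, , ]`. Pixel coordinates are 0-based `(row, column)`
#' throughout the package's reporting functions.
#'
#' @param frames numeric array with `dim = c(T, H, W)`, `T >= 2`
#' @param frame_rate sampling rate in frames per second (Hz), `> 0`
#' @param ground_truth optional tibble of injected components (frequency_hz,
#'   amplitude, region), attached by the synthetic generator
#' @return a `video_cube` object
#' @export
video_cube <- function(frames, frame_rate, ground_truth = NULL) {
  stop_if_not(is.array(frames) && length(dim(frames)) == 3,
              "`frames` must be a 3-d array (T x H x W)")
  stop_if_not(dim(frames)[1] >= 2, "a video cube needs at least 2 frames")
  stop_if_not(is.numeric(frame_rate) && length(frame_rate) == 1 && frame_rate > 0,
              "`frame_rate` must be a positive scalar (Hz)")
  structure(frames,
            frame_rate = frame_rate,
            ground_truth = ground_truth,
            class = c("video_cube", "array"))
}

#' @export
print.video_cube <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<video_cube> %d frames of %d x %d px @ %g fps (%.2f s)\n",
              d[1], d[2], d[3], attr(x, "frame_rate"), d[1] / attr(x, "frame_rate")))
  gt <- attr(x, "ground_truth")
  if (!is.null(gt)) cat(sprintf("  ground truth: %d injected component(s)\n", nrow(gt)))
  invisible(x)
}

n_frames    <- function(v) dim(v)[1]
frame_rate  <- function(v) attr(v, "frame_rate")

# T x P matrix view (columns are pixels in column-major (row, col) order);
# cheap because the array is already stored frame-index fastest.
cube_matrix <- function(v) {
  d <- dim(v)
  matrix(as.numeric(v), nrow = d[1], ncol = d[2] * d[3])
}

#' Rectangular central region mask
#'
#' Convenience mask for the head-like region of interest: a centred rectangle
#' covering `frac` of each image dimension.
#'
#' @param h,w image size in pixels
#' @param frac fraction of each dimension covered (default 0.5)
#' @return logical `h x w` matrix
#' @export
central_mask <- function(h, w, frac = 0.5) {
  stop_if_not(frac > 0 && frac <= 1, "`frac` must be in (0, 1]")
  m <- matrix(FALSE, h, w)
  rh <- max(1L, round(h * frac)); rw <- max(1L, round(w * frac))
  r0 <- floor((h - rh) / 2) + 1L; c0 <- floor((w - rw) / 2) + 1L
  m[r0:(r0 + rh - 1L), c0:(c0 + rw - 1L)] <- TRUE
  m
}
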