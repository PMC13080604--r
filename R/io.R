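#' Write a video cube as a multi-page TIFF with a JSON sidecar
#'
#' Frames are stored as 32-bit float pages rescaled to [0, 1]; the affine
#' rescaling, the frame rate and any injected ground truth go into a JSON
#' sidecar (`<path>.json`) so the cube round-trips exactly up to float
#' precision.
#'
#' @param video a [video_cube()]
#' @param path output TIFF path
#' @return `path`, invisibly
#' @export
write_video_tiff <- function(video, path) {
  stop_if_not(inherits(video, "video_cube"), "`video` must be a video_cube")
  lo <- min(video); hi <- max(video)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(n_frames(video)),
                  function(t) (unclass(video)[t, , ] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  gt <- attr(video, "ground_truth")
  side <- list(frame_rate = frame_rate(video), offset = lo, scale = scale,
               ground_truth = gt)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' Read a video cube written by [write_video_tiff()]
#'
#' @param path TIFF path (the JSON sidecar `<path>.json` must sit next to it)
#' @return a [video_cube()]
#' @export
read_video_tiff <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  tt <- length(pages); h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  cube <- array(0, dim = c(tt, h, w))
  for (t in seq_len(tt)) cube[t, , ] <- pages[[t]] * side$scale + side$offset
  gt <- side$ground_truth
  video_cube(cube, side$frame_rate,
             ground_truth = if (!is.null(gt)) tibble::as_tibble(gt))
}

#' Write a cohort table to CSV
#'
#' Plain-text export of a [generate_cohort()] table (or any subject tibble).
#' @param cohort data frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort CSV
#' @param path CSV path
#' @return tibble
#' @export
read_cohort_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Serialize calibration and tier thresholds to JSON
#'
#' @param calibration a [fit_temperature()] model
#' @param thresholds optional [fit_tier_thresholds()] result
#' @param path output JSON path
#' @return `path`, invisibly
#' @export
write_calibration_json <- function(calibration, thresholds = NULL, path) {
  obj <- list(temperature = calibration$temperature, nll = calibration$nll)
  if (!is.null(thresholds)) obj$tier_thresholds <- list(t1 = thresholds$t1[1],
                                                        t2 = thresholds$t2[1])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
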