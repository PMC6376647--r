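#' End-to-end cell detection on a z-stack
#'
#' The exact composition of the pipeline's tested pieces, with no
#' hidden post-processing: select and normalize the plane triplet,
#' predict the confidence heatmap, extract local peaks. The peak
#' parameters default to the auto-labeling values (threshold 0.2,
#' minimum distance 5 px); both are independent settings here.
#'
#' @param detector A trained `cell_detector`.
#' @param stack A [zstack()].
#' @param triplet_start First plane of the input triplet; defaults to
#'   the stack's in-focus plane (plane 13 in the reference geometry,
#'   giving planes 13--15).
#' @param peak_threshold,peak_min_distance Passed to [find_peaks()].
#' @return List with `detections` (a [detection_set()]) and `heatmap`
#'   (kept for inspection or archival).
#' @export
detect_cells <- function(detector, stack,
                         triplet_start = stack$in_focus_index,
                         peak_threshold = 0.2, peak_min_distance = 5) {
  stopifnot(inherits(detector, "cell_detector"), inherits(stack, "zstack"))
  triplet <- select_triplet(stack, triplet_start)
  heatmap <- predict_heatmap(detector, triplet)
  detections <- find_peaks(heatmap, peak_threshold, peak_min_distance)
  list(detections = detections, heatmap = heatmap)
}

#' Write a heatmap as a float TIFF
#'
#' @param heatmap H x W matrix in \[0, 1\].
#' @param path Output path; stored as 32-bit float, single page.
#' @return `path`, invisibly.
#' @export
write_heatmap <- function(heatmap, path) {
  m <- unclass(as.matrix(heatmap))
  m[m < 0] <- 0
  m[m > 1] <- 1
  tiff::writeTIFF(m, path, bits.per.sample = 32L)
  invisible(path)
}
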