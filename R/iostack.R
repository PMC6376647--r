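#' Construct a z-stack object
#'
#' A z-stack is an ordered set of co-registered focal-plane images of
#' one field of view. Planes are stored as an H x W x n_planes array
#' (unit-scaled intensities); plane indices are 1-based so that "the
#' 13th focal plane is in focus" reads naturally, while pixel
#' coordinates elsewhere in the package are 0-based (row, col).
#'
#' @param planes H x W x n_planes numeric array.
#' @param plane_spacing_um Distance between adjacent focal planes in
#'   micrometres (10 for the acquisition geometry this package models).
#' @param in_focus_index 1-based index of the most-focused plane.
#' @return An object of class `zstack`.
#' @export
zstack <- function(planes, plane_spacing_um = 10, in_focus_index = 1L) {
  if (length(dim(planes)) == 2L) planes <- array(planes, c(dim(planes), 1L))
  stopifnot(is.array(planes), length(dim(planes)) == 3L)
  n <- dim(planes)[3]
  in_focus_index <- as.integer(in_focus_index)
  if (n < 1L) stop("a z-stack needs at least one plane", call. = FALSE)
  if (in_focus_index < 1L || in_focus_index > n)
    stop(sprintf("in_focus_index %d outside 1..%d", in_focus_index, n),
         call. = FALSE)
  structure(list(planes = planes, plane_spacing_um = plane_spacing_um,
                 in_focus_index = in_focus_index),
            class = "zstack")
}

#' @export
print.zstack <- function(x, ...) {
  d <- dim(x$planes)
  cat(sprintf("<zstack> %d planes of %dx%d px, %g um spacing, plane %d in focus\n",
              d[3], d[1], d[2], x$plane_spacing_um, x$in_focus_index))
  invisible(x)
}

#' Number of planes / image shape of a z-stack
#' @param stack A `zstack`.
#' @return `n_planes()`: integer count; `image_shape()`: `c(height, width)`.
#' @export
n_planes <- function(stack) dim(stack$planes)[3]

#' @rdname n_planes
#' @export
image_shape <- function(stack) dim(stack$planes)[1:2]

#' Read a focus stack from disk
#'
#' The canonical container is a multi-page TIFF with one page per focal
#' plane, in acquisition order. A directory of per-plane images
#' (lexicographically ordered TIFF/PNG files) is accepted as a fallback
#' dialect.
#'
#' @param path Multi-page TIFF file, or a directory of per-plane images.
#' @param plane_spacing_um Plane spacing in micrometres.
#' @param in_focus_index 1-based index of the in-focus plane.
#' @return A [zstack()].
#' @export
read_zstack <- function(path, plane_spacing_um = 10, in_focus_index = 13L) {
  if (!file.exists(path)) stop("no such file or directory: ", path, call. = FALSE)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(tif|tiff|png)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L)
      stop("directory contains no TIFF/PNG plane images: ", path, call. = FALSE)
    pages <- lapply(files, function(f) {
      if (grepl("\\.png$", f, ignore.case = TRUE)) png::readPNG(f)
      else tiff::readTIFF(f)
    })
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
  }
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p[, , 1] else p  # collapse RGB to first channel
  })
  shapes <- vapply(pages, dim, integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
    stop("stack pages have non-uniform shapes", call. = FALSE)
  planes <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  zstack(planes, plane_spacing_um, in_focus_index)
}

#' Write a z-stack as a multi-page TIFF
#'
#' Intensities are clipped to \[0, 1\] and stored as 32-bit floats, so
#' unit-scaled stacks round-trip to single precision.
#'
#' @param stack A [zstack()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_zstack <- function(stack, path) {
  stopifnot(inherits(stack, "zstack"))
  pages <- lapply(seq_len(n_planes(stack)), function(i) {
    p <- stack$planes[, , i]
    p[p < 0] <- 0
    p[p > 1] <- 1
    p
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' Extract and normalize a triplet of consecutive focal planes
#'
#' The detector consumes three consecutive focal planes as a 3-channel
#' input — the in-focus plane and the two planes above it in the
#' reference geometry (planes 13, 14 and 15 of a 25-plane stack).
#' Each channel is standardized per image to zero mean and unit
#' variance, making the input robust to exposure differences between
#' cultivations; the identical transform is applied at train and
#' predict time. Use `normalize = FALSE` to obtain the raw slice
#' (bit-identical to subsetting the stack array).
#'
#' @param stack A [zstack()].
#' @param start_index 1-based index of the first plane of the triplet;
#'   defaults to the stack's in-focus plane.
#' @param normalize Standardize each channel? Default `TRUE`.
#' @return An object of class `plane_triplet` with fields `channels`
#'   (H x W x 3 array) and `source_plane_indices`.
#' @export
select_triplet <- function(stack, start_index = stack$in_focus_index,
                           normalize = TRUE) {
  stopifnot(inherits(stack, "zstack"))
  start_index <- as.integer(start_index)
  np <- n_planes(stack)
  if (start_index < 1L || start_index + 2L > np)
    stop(sprintf("triplet %d..%d outside stack with %d planes",
                 start_index, start_index + 2L, np), call. = FALSE)
  ch <- stack$planes[, , start_index:(start_index + 2L), drop = FALSE]
  if (normalize) {
    for (i in 1:3) {
      v <- ch[, , i]
      s <- stats::sd(v)
      ch[, , i] <- if (s > 0) (v - mean(v)) / s else v - mean(v)
    }
  }
  plane_triplet(ch, start_index:(start_index + 2L), normalized = normalize)
}

#' Construct a plane-triplet object
#'
#' @param channels H x W x 3 array of intensities.
#' @param source_plane_indices Three strictly consecutive 1-based plane
#'   indices.
#' @param normalized Whether channels have been standardized.
#' @return An object of class `plane_triplet`.
#' @export
plane_triplet <- function(channels, source_plane_indices = 1:3,
                          normalized = FALSE) {
  stopifnot(is.array(channels), length(dim(channels)) == 3L,
            dim(channels)[3] == 3L)
  idx <- as.integer(source_plane_indices)
  if (length(idx) != 3L || any(diff(idx) != 1L))
    stop("source_plane_indices must be three consecutive indices",
         call. = FALSE)
  structure(list(channels = channels, source_plane_indices = idx,
                 normalized = isTRUE(normalized)),
            class = "plane_triplet")
}

#' Construct a point-annotation set
#'
#' Cell centres are 0-based (row, col) pixel coordinates, row-major.
#' Provenance records whether the points are manual annotations or
#' pseudo-labels produced by auto-labeling.
#'
#' @param points Two-column matrix or data.frame of (row, col)
#'   coordinates; may have zero rows.
#' @param image_shape `c(height, width)` of the annotated image.
#' @param provenance `"manual"` or `"pseudo"`.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(points, image_shape, provenance = "manual") {
  provenance <- match.arg(provenance, c("manual", "pseudo"))
  pts <- as.matrix(points)
  if (length(pts) == 0L) pts <- matrix(numeric(0), 0, 2)
  if (ncol(pts) != 2L) stop("points must have two columns (row, col)",
                            call. = FALSE)
  storage.mode(pts) <- "double"
  colnames(pts) <- c("row", "col")
  image_shape <- as.integer(image_shape)
  stopifnot(length(image_shape) == 2L, all(image_shape >= 1L))
  if (nrow(pts) > 0L) {
    oob <- pts[, 1] < 0 | pts[, 1] > image_shape[1] - 1 |
           pts[, 2] < 0 | pts[, 2] > image_shape[2] - 1
    if (any(oob))
      stop(sprintf("%d point(s) outside the %dx%d image", sum(oob),
                   image_shape[1], image_shape[2]), call. = FALSE)
    if (anyDuplicated(pts))
      stop("duplicate annotation points", call. = FALSE)
  }
  structure(list(points = pts, image_shape = image_shape,
                 provenance = provenance),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d %s cell centre(s) on a %dx%d image\n",
              nrow(x$points), x$provenance, x$image_shape[1], x$image_shape[2]))
  invisible(x)
}

#' Number of annotated cells
#' @param ann An `annotation_set` or `detection_set`.
#' @return Integer count.
#' @export
n_cells <- function(ann) nrow(ann$points)

#' Construct a detection set
#'
#' Output of heatmap peak extraction: point coordinates plus the
#' heatmap confidence at each peak.
#'
#' @param points Two-column matrix of (row, col) coordinates.
#' @param confidences Numeric vector in \[0, 1\], one per point.
#' @return An object of class `detection_set`.
#' @export
detection_set <- function(points, confidences = rep(1, NROW(points))) {
  pts <- as.matrix(points)
  if (length(pts) == 0L) pts <- matrix(numeric(0), 0, 2)
  storage.mode(pts) <- "double"
  colnames(pts) <- c("row", "col")
  if (nrow(pts) != length(confidences))
    stop("one confidence per point required", call. = FALSE)
  if (length(confidences) && (min(confidences) < 0 || max(confidences) > 1))
    stop("confidences must lie in [0, 1]", call. = FALSE)
  structure(list(points = pts, confidences = as.numeric(confidences)),
            class = "detection_set")
}

#' @export
print.detection_set <- function(x, ...) {
  cat(sprintf("<detection_set> %d detection(s)\n", nrow(x$points)))
  invisible(x)
}

#' Read / write point annotations and detections as CSV
#'
#' Annotations use a `row,col` header; detections additionally carry a
#' `confidence` column. Writing then reading reproduces the points
#' exactly.
#'
#' @param path CSV file path.
#' @param image_shape `c(height, width)` used for bounds checking.
#' @param provenance Provenance flag for the returned set.
#' @return `read_annotations()` an [annotation_set()];
#'   `read_detections()` a [detection_set()]; the writers return `path`
#'   invisibly.
#' @export
read_annotations <- function(path, image_shape, provenance = "manual") {
  df <- utils::read.csv(path)
  if (!all(c("row", "col") %in% names(df)))
    stop("annotation CSV needs a 'row,col' header: ", path, call. = FALSE)
  if (nrow(df) && (!is.numeric(df$row) || !is.numeric(df$col) ||
                   anyNA(df$row) || anyNA(df$col)))
    stop("malformed annotation rows in ", path, call. = FALSE)
  annotation_set(cbind(df$row, df$col), image_shape, provenance)
}

#' @rdname read_annotations
#' @param ann An [annotation_set()].
#' @export
write_annotations <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_set"))
  utils::write.csv(as.data.frame(ann$points), path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_annotations
#' @export
read_detections <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("row", "col", "confidence") %in% names(df)))
    stop("detection CSV needs a 'row,col,confidence' header: ", path,
         call. = FALSE)
  detection_set(cbind(df$row, df$col), df$confidence)
}

#' @rdname read_annotations
#' @param det A [detection_set()].
#' @export
write_detections <- function(det, path) {
  stopifnot(inherits(det, "detection_set"))
  df <- data.frame(row = det$points[, 1], col = det$points[, 2],
                   confidence = det$confidences)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
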