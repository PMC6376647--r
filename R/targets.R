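# Training targets: point annotations rasterized as small disks.
# A pixel (y, x) belongs to the disk of a cell at (r0, c0) iff
# (y - r0)^2 + (x - c0)^2 <= radius^2 — the same convention as a
# morphological disk structuring element, and the same one used when
# dilating pseudo-label points during domain adaptation.

# 0-based (dy, dx) offsets of the lattice disk of radius r.
disk_offsets <- function(r) {
  s <- -r:r
  g <- expand.grid(dy = s, dx = s)
  g <- g[g$dy^2 + g$dx^2 <= r^2, , drop = FALSE]
  as.matrix(g)
}

#' Pixel count of a lattice disk
#'
#' Number of integer lattice points (x, y) with x^2 + y^2 <= r^2:
#' 197 for the default training-target radius 8, 113 for the radius-6
#' pseudo-label disks.
#'
#' @param r Disk radius in pixels.
#' @return Integer pixel count.
#' @export
disk_pixel_count <- function(r) nrow(disk_offsets(r))

# Paint disks into a logical H x W matrix, clipping at borders.
paint_disks <- function(points, radii, shape) {
  m <- matrix(FALSE, shape[1], shape[2])
  if (NROW(points) == 0L) return(m)
  for (i in seq_len(nrow(points))) {
    off <- disk_offsets(radii[i])
    yy <- round(points[i, 1]) + off[, "dy"]
    xx <- round(points[i, 2]) + off[, "dx"]
    keep <- yy >= 0 & yy < shape[1] & xx >= 0 & xx < shape[2]
    m[cbind(yy[keep] + 1L, xx[keep] + 1L)] <- TRUE
  }
  m
}

# Would the radius-ri disk at pi and radius-rj disk at pj share or
# 8-neighbour any pixel? Checked on the rasterized disks (Chebyshev
# gap <= 1 between any pair of foreground pixels).
disks_touch <- function(pi, ri, pj, rj) {
  if (sqrt(sum((pi - pj)^2)) > ri + rj + 2) return(FALSE)
  oi <- disk_offsets(ri)
  oj <- disk_offsets(rj)
  ay <- round(pi[1]) + oi[, "dy"]; ax <- round(pi[2]) + oi[, "dx"]
  by <- round(pj[1]) + oj[, "dy"]; bx <- round(pj[2]) + oj[, "dx"]
  dy <- abs(outer(ay, by, "-")); dx <- abs(outer(ax, bx, "-"))
  any(pmax(dy, dx) <= 1)
}

#' Rasterize annotations into a binary training-target mask
#'
#' Each cell is marked with a disk of radius `max_radius` (default 8, a
#' trade-off between cell-separation capability and class balance). If
#' the disks of two cells would touch — share or 8-neighbour a pixel —
#' both radii are reduced for better separation: for every touching
#' pair at centre distance d, both cells' radii are capped at
#' `floor((d - 1) / 2)` (never below 1), taking the minimum over all
#' conflicting pairs per cell. A safeguard pass then decrements any
#' still-touching pair (diagonal adjacency can survive the analytic
#' cap) until all cells form distinct 8-connected components or radii
#' bottom out at 1 px.
#'
#' @param ann An [annotation_set()].
#' @param max_radius Maximum disk radius in pixels (default 8).
#' @return An object of class `target_mask`: list with `mask` (logical
#'   H x W matrix), `max_radius`, and `per_cell_radius`.
#' @export
make_target_mask <- function(ann, max_radius = 8L) {
  stopifnot(inherits(ann, "annotation_set"), max_radius >= 1)
  max_radius <- as.integer(max_radius)
  pts <- ann$points
  n <- nrow(pts)
  radii <- rep(max_radius, n)
  if (n >= 2L) {
    dmat <- as.matrix(stats::dist(pts))
    cand <- which(upper.tri(dmat) & dmat <= 2 * max_radius + 2, arr.ind = TRUE)
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (disks_touch(pts[i, ], max_radius, pts[j, ], max_radius)) {
        r <- max(1L, as.integer(floor((dmat[i, j] - 1) / 2)))
        radii[i] <- min(radii[i], r)
        radii[j] <- min(radii[j], r)
      }
    }
    # safeguard: resolve residual (diagonal) adjacency
    repeat {
      changed <- FALSE
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if ((radii[i] > 1L || radii[j] > 1L) &&
            disks_touch(pts[i, ], radii[i], pts[j, ], radii[j])) {
          radii[i] <- max(1L, radii[i] - 1L)
          radii[j] <- max(1L, radii[j] - 1L)
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  structure(list(mask = paint_disks(pts, radii, ann$image_shape),
                 max_radius = max_radius, per_cell_radius = radii),
            class = "target_mask")
}

#' @export
print.target_mask <- function(x, ...) {
  cat(sprintf("<target_mask> %dx%d, %d cell disk(s), %d foreground px\n",
              nrow(x$mask), ncol(x$mask), length(x$per_cell_radius),
              sum(x$mask)))
  invisible(x)
}

#' Rescale an image/annotation pair
#'
#' Resizes the plane triplet and its annotations by a common factor —
#' the augmentation used to double the training data by shrinking the
#' source images to 75 % of their size so the detector also sees
#' smaller cells. The target-mask radius shrinks in the same
#' proportion: `round(factor * max_radius)`, e.g. 8 px becomes 6 px at
#' factor 0.75.
#'
#' @param triplet A [plane_triplet()].
#' @param ann The matching [annotation_set()].
#' @param factor Scale factor in (0, 1].
#' @param max_radius Mask radius before scaling (default 8).
#' @return List with `triplet`, `ann`, and `new_max_radius`.
#' @export
rescale_pair <- function(triplet, ann, factor, max_radius = 8L) {
  stopifnot(inherits(triplet, "plane_triplet"),
            inherits(ann, "annotation_set"))
  if (factor <= 0) stop("factor must be positive", call. = FALSE)
  if (factor > 1) stop("factor must be <= 1", call. = FALSE)
  d <- dim(triplet$channels)
  nh <- max(1L, as.integer(round(factor * d[1])))
  nw <- max(1L, as.integer(round(factor * d[2])))
  ch <- array(0, c(nh, nw, 3))
  for (i in 1:3)
    ch[, , i] <- EBImage::imageData(
      EBImage::resize(EBImage::Image(triplet$channels[, , i]),
                      w = nh, h = nw))
  pts <- round(ann$points * factor)
  pts[, 1] <- pmin(pts[, 1], nh - 1L)
  pts[, 2] <- pmin(pts[, 2], nw - 1L)
  pts <- unique(pts)
  list(triplet = plane_triplet(ch, triplet$source_plane_indices,
                               triplet$normalized),
       ann = annotation_set(pts, c(nh, nw), ann$provenance),
       new_max_radius = as.integer(round(factor * max_radius)))
}

#' Background-to-foreground class balance of target masks
#'
#' Pooled ratio of background to cell pixels over a collection of
#' masks. The reference acquisition (twelve 1196x1596 images, 5878
#' cells, radius-8 disks) gives roughly a 20:1 balance, manageable for
#' unweighted binary cross-entropy.
#'
#' @param masks A `target_mask` or list of them.
#' @return List with `ratio` (background px / foreground px; `Inf` when
#'   degenerate), `degenerate` flag, `background_px` and
#'   `foreground_px`.
#' @export
class_balance <- function(masks) {
  if (inherits(masks, "target_mask")) masks <- list(masks)
  stopifnot(length(masks) >= 1L,
            all(vapply(masks, inherits, logical(1), "target_mask")))
  fg <- sum(vapply(masks, function(m) sum(m$mask), numeric(1)))
  tot <- sum(vapply(masks, function(m) length(m$mask), numeric(1)))
  bg <- tot - fg
  list(ratio = if (fg > 0) bg / fg else Inf, degenerate = fg == 0,
       background_px = bg, foreground_px = fg)
}

#' Write / read a binary target mask
#'
#' Masks persist as single-page binary TIFF images.
#'
#' @param mask A `target_mask` or logical matrix.
#' @param path File path.
#' @return `write_mask` returns `path` invisibly; `read_mask` a logical
#'   matrix.
#' @export
write_mask <- function(mask, path) {
  m <- if (inherits(mask, "target_mask")) mask$mask else mask
  tiff::writeTIFF(m * 1, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  tiff::readTIFF(path) > 0.5
}
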