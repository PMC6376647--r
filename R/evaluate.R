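#' Match detections to ground-truth annotations
#'
#' A detection and a ground-truth point may match when their Euclidean
#' distance is strictly below `max_dist` (a distance of exactly
#' `max_dist` is not a detection). When several candidates fall within
#' the threshold, only the closest is accepted: all candidate pairs
#' are sorted by ascending distance and accepted greedily, each
#' detection and each ground-truth point used at most once. The greedy
#' order makes the rule deterministic and symmetric in the two sets.
#'
#' @param pred A [detection_set()].
#' @param gt An [annotation_set()] on the same image.
#' @param max_dist Matching radius in pixels (default 20).
#' @return An object of class `match_result` with counts `tp`, `fp`,
#'   `fn`, a `pairs` data.frame (pred_idx, gt_idx, distance), and the
#'   two point sets.
#' @export
match_detections <- function(pred, gt, max_dist = 20) {
  stopifnot(inherits(pred, "detection_set"), inherits(gt, "annotation_set"))
  np <- nrow(pred$points)
  ng <- nrow(gt$points)
  pairs <- data.frame(pred_idx = integer(0), gt_idx = integer(0),
                      distance = numeric(0))
  if (np > 0L && ng > 0L) {
    d <- sqrt(outer(pred$points[, 1], gt$points[, 1], "-")^2 +
              outer(pred$points[, 2], gt$points[, 2], "-")^2)
    cand <- which(d < max_dist, arr.ind = TRUE)
    if (nrow(cand)) {
      dist <- d[cand]
      ord <- order(dist, cand[, 1], cand[, 2])
      used_p <- logical(np)
      used_g <- logical(ng)
      for (k in ord) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (!used_p[i] && !used_g[j]) {
          used_p[i] <- TRUE
          used_g[j] <- TRUE
          pairs <- rbind(pairs, data.frame(pred_idx = i, gt_idx = j,
                                           distance = dist[k]))
        }
      }
    }
  }
  structure(list(tp = nrow(pairs), fp = np - nrow(pairs),
                 fn = ng - nrow(pairs), pairs = pairs,
                 pred = pred, gt = gt),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  s <- compute_scores(x)
  cat(sprintf(
    "<match_result> TP %d  FP %d  FN %d | precision %.3f recall %.3f F1 %.3f\n",
    x$tp, x$fp, x$fn, s$precision, s$recall, s$f1))
  invisible(x)
}

#' Precision, recall and F1 from matched detections
#'
#' precision = TP / (TP + FP), recall = TP / (TP + FN), F1 =
#' 2 (precision x recall) / (precision + recall). Zero-denominator
#' conventions: with no detections, precision is 1 when there is also
#' no ground truth and 0 otherwise (symmetrically for recall); F1 is 1
#' in the all-empty case and 0 whenever precision + recall is 0.
#'
#' @param m A `match_result`, or a list of them (counts are pooled
#'   before computing the scores).
#' @return List of class `scores` with `precision`, `recall`, `f1`,
#'   and the pooled counts.
#' @export
compute_scores <- function(m) {
  if (inherits(m, "match_result")) m <- list(m)
  stopifnot(all(vapply(m, inherits, logical(1), "match_result")))
  tp <- sum(vapply(m, `[[`, numeric(1), "tp"))
  fp <- sum(vapply(m, `[[`, numeric(1), "fp"))
  fn <- sum(vapply(m, `[[`, numeric(1), "fn"))
  precision <- if (tp + fp > 0) tp / (tp + fp) else as.numeric(fn == 0)
  recall <- if (tp + fn > 0) tp / (tp + fn) else as.numeric(fp == 0)
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall)
  else as.numeric(tp + fp + fn == 0)
  structure(list(precision = precision, recall = recall, f1 = f1,
                 tp = tp, fp = fp, fn = fn),
            class = "scores")
}

#' @export
print.scores <- function(x, ...) {
  cat(sprintf("precision %.4f  recall %.4f  F1 %.4f (TP %d FP %d FN %d)\n",
              x$precision, x$recall, x$f1, x$tp, x$fp, x$fn))
  invisible(x)
}

#' Kernel density map of cell locations
#'
#' Smooths discrete cell centres into a local-neighbourhood density:
#' each cell contributes one unit-mass isotropic normal kernel, so the
#' map sums (times unit pixel area) to the number of cells when the
#' image extends well beyond them.
#'
#' @param points Two-column (row, col) matrix of 0-based coordinates.
#' @param shape `c(height, width)` of the map.
#' @param sigma Kernel standard deviation in pixels (default 50).
#' @return H x W numeric matrix.
#' @export
density_map <- function(points, shape, sigma = 50) {
  dm <- matrix(0, shape[1], shape[2])
  ys <- seq_len(shape[1]) - 1
  xs <- seq_len(shape[2]) - 1
  for (i in seq_len(NROW(points)))
    dm <- dm + outer(stats::dnorm(ys, points[i, 1], sigma),
                     stats::dnorm(xs, points[i, 2], sigma))
  dm
}

#' Density-stratified detection accuracy
#'
#' Computes a kernel density map of the ground-truth cells (normal
#' kernel, sigma = 50 px by default) and divides its value range into
#' `n_bins` intervals of equal density range — not equal area, and not
#' equal cell count. Every ground-truth cell is assigned to the bin of
#' the density at its own pixel; detections (matched or false) are
#' assigned by the density at the detection's pixel. Per-bin recall
#' comes from the ground-truth assignments, per-bin precision from the
#' detection assignments.
#'
#' @param results A `match_result` or list of them (one per image).
#'   With several images, bin edges span the pooled density range.
#' @param sigma Kernel bandwidth in pixels (default 50).
#' @param n_bins Number of equal-range density bins (default 5).
#' @return An object of class `density_profile`: `bin_edges` and a
#'   `per_bin` data.frame (bin, density_lo, density_hi, n_cells,
#'   n_detections, precision, recall, f1).
#' @export
density_profile <- function(results, sigma = 50, n_bins = 5L) {
  if (inherits(results, "match_result")) results <- list(results)
  stopifnot(all(vapply(results, inherits, logical(1), "match_result")),
            n_bins >= 1L)
  maps <- lapply(results, function(m)
    density_map(m$gt$points, m$gt$image_shape, sigma))
  rng <- range(unlist(lapply(maps, range)))
  if (diff(rng) == 0) rng[2] <- rng[1] + .Machine$double.eps
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin_of <- function(map, pts) {
    if (NROW(pts) == 0L) return(integer(0))
    v <- map[cbind(round(pts[, 1]) + 1L, round(pts[, 2]) + 1L)]
    findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
  }
  n_gt <- n_tp_gt <- n_det <- n_tp_det <- integer(n_bins)
  for (k in seq_along(results)) {
    m <- results[[k]]
    gb <- bin_of(maps[[k]], m$gt$points)
    db <- bin_of(maps[[k]], m$pred$points)
    matched_gt <- m$pairs$gt_idx
    matched_pred <- m$pairs$pred_idx
    for (b in seq_len(n_bins)) {
      n_gt[b] <- n_gt[b] + sum(gb == b)
      n_tp_gt[b] <- n_tp_gt[b] + sum(gb[matched_gt] == b)
      n_det[b] <- n_det[b] + sum(db == b)
      n_tp_det[b] <- n_tp_det[b] + sum(db[matched_pred] == b)
    }
  }
  per_bin <- data.frame(
    bin = seq_len(n_bins),
    density_lo = edges[-(n_bins + 1L)],
    density_hi = edges[-1L],
    n_cells = n_gt,
    n_detections = n_det,
    precision = ifelse(n_det > 0, n_tp_det / n_det, NA_real_),
    recall = ifelse(n_gt > 0, n_tp_gt / n_gt, NA_real_))
  pb <- per_bin$precision + per_bin$recall
  per_bin$f1 <- ifelse(!is.na(pb) & pb > 0,
                       2 * per_bin$precision * per_bin$recall / pb,
                       ifelse(is.na(pb), NA_real_, 0))
  structure(list(bin_edges = edges, per_bin = per_bin, sigma = sigma),
            class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("<density_profile> sigma %g px, %d equal-range bins\n",
              x$sigma, nrow(x$per_bin)))
  print(x$per_bin, row.names = FALSE, digits = 3)
  invisible(x)
}
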