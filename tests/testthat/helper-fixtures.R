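# Shared fixtures, built in code at test time.

# Small z-stack with known contents: plane p is a constant p/10 image.
make_constant_stack <- function(n_planes = 5L, shape = c(12L, 16L)) {
  planes <- array(0, c(shape, n_planes))
  for (p in seq_len(n_planes)) planes[, , p] <- p / 10
  zstack(planes, plane_spacing_um = 10, in_focus_index = (n_planes + 1L) %/% 2L)
}

random_points <- function(n, shape) {
  if (n == 0L) return(matrix(numeric(0), 0, 2))
  unique(cbind(sample.int(shape[1], n, replace = TRUE) - 1L,
               sample.int(shape[2], n, replace = TRUE) - 1L))
}

# Brute-force per-pixel disk-union oracle for target masks.
oracle_disk_mask <- function(points, radii, shape) {
  m <- matrix(FALSE, shape[1], shape[2])
  for (y in 0:(shape[1] - 1)) for (x in 0:(shape[2] - 1))
    for (i in seq_len(NROW(points)))
      if ((y - points[i, 1])^2 + (x - points[i, 2])^2 <= radii[i]^2)
        m[y + 1, x + 1] <- TRUE
  m
}

# Brute-force peak oracle: all supra-threshold 8-neighbourhood local
# maxima (plateaus collapsed to the centroid-nearest pixel), kept
# greedily by descending value with min-distance suppression.
oracle_find_peaks <- function(v, threshold, min_distance) {
  H <- nrow(v); W <- ncol(v)
  is_cand <- matrix(FALSE, H, W)
  for (y in 1:H) for (x in 1:W) {
    if (v[y, x] < threshold) next
    ok <- TRUE
    for (dy in -1:1) for (dx in -1:1) {
      ny <- y + dy; nx <- x + dx
      if ((dy | dx) && ny >= 1 && ny <= H && nx >= 1 && nx <= W &&
          v[ny, nx] > v[y, x]) ok <- FALSE
    }
    is_cand[y, x] <- ok
  }
  if (!any(is_cand)) return(matrix(numeric(0), 0, 2))
  # plateau components (8-connectivity, equal values by construction)
  lab <- matrix(0L, H, W)
  nl <- 0L
  for (y in 1:H) for (x in 1:W) {
    if (!is_cand[y, x] || lab[y, x]) next
    nl <- nl + 1L
    q <- list(c(y, x)); lab[y, x] <- nl
    while (length(q)) {
      p <- q[[1]]; q <- q[-1]
      for (dy in -1:1) for (dx in -1:1) {
        ny <- p[1] + dy; nx <- p[2] + dx
        if (ny >= 1 && ny <= H && nx >= 1 && nx <= W &&
            is_cand[ny, nx] && !lab[ny, nx]) {
          lab[ny, nx] <- nl; q[[length(q) + 1]] <- c(ny, nx)
        }
      }
    }
  }
  reps <- t(vapply(seq_len(nl), function(l) {
    idx <- which(lab == l, arr.ind = TRUE)
    cen <- colMeans(idx)
    d2 <- (idx[, 1] - cen[1])^2 + (idx[, 2] - cen[2])^2
    as.numeric(idx[order(d2, idx[, 1], idx[, 2])[1], ])
  }, numeric(2)))
  vals <- v[reps]
  ord <- order(-vals, reps[, 1], reps[, 2])
  reps <- reps[ord, , drop = FALSE]
  kept <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(reps))) {
    p <- reps[i, ]
    if (nrow(kept) == 0 ||
        min(sqrt((kept[, 1] - p[1])^2 + (kept[, 2] - p[2])^2)) >= min_distance)
      kept <- rbind(kept, p)
  }
  unname(kept - 1)  # 0-based
}

# A small detector trained once on the source preset and cached for
# the whole test run (training is the expensive step).
trained_detector_cache <- new.env(parent = emptyenv())
get_trained_detector <- function() {
  if (!is.null(trained_detector_cache$det)) return(trained_detector_cache$det)
  pairs <- training_pairs_from_samples(
    lapply(1:6, function(i) simulate_sample(domain_preset("sourcelike"),
                                            seed = 4000 + i)),
    max_radius = 6)
  set.seed(42)
  det <- build_detector(model_config(depth = 3, base_filters = 8))
  sch <- train_schedule(total_epochs = 20L, cycle_length = 10L,
                        patch_sizes = c(64L, 96L), patches_per_image = 4L)
  r <- train_supervised(det, pairs, sch, seed = 42)
  trained_detector_cache$det <- r$detector
  r$detector
}
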