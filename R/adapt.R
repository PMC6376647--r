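#' Domain-adaptation configuration
#'
#' Defaults follow the reference pipeline: six 10-epoch cycles; at
#' each cycle the current model predicts four randomly selected
#' unlabeled target-domain images, local heatmap peaks above 0.2 (a
#' deliberately low threshold, so weak detections also become training
#' signal) with at least 5 px between peaks are taken as cells, and
#' each peak is dilated into a radius-6 disk to form a pseudo target
#' mask. Half of each cycle's training data is pseudo-labeled target
#' patches, half annotated source patches — the safeguard that keeps
#' false detections from amplifying over iterations.
#'
#' @param n_cycles Pseudo-label regenerations (default 6).
#' @param epochs_per_cycle Training epochs per cycle (default 10).
#' @param peak_threshold Minimum heatmap value of a peak (default 0.2).
#' @param peak_min_distance Minimum Euclidean distance between peaks in
#'   px (default 5).
#' @param pseudo_radius Dilation radius of pseudo targets in px
#'   (default 6).
#' @param n_target_images_per_cycle Target images predicted per cycle
#'   (default 4).
#' @param source_fraction Fraction of annotated source patches in the
#'   mixed pool (default 0.5).
#' @return An object of class `adapt_config`.
#' @export
adapt_config <- function(n_cycles = 6L, epochs_per_cycle = 10L,
                         peak_threshold = 0.2, peak_min_distance = 5,
                         pseudo_radius = 6L,
                         n_target_images_per_cycle = 4L,
                         source_fraction = 0.5) {
  stopifnot(n_cycles >= 1, epochs_per_cycle >= 1,
            peak_threshold > 0, peak_threshold < 1,
            peak_min_distance >= 1, pseudo_radius >= 1,
            n_target_images_per_cycle >= 1,
            source_fraction > 0, source_fraction < 1)
  structure(list(n_cycles = as.integer(n_cycles),
                 epochs_per_cycle = as.integer(epochs_per_cycle),
                 peak_threshold = peak_threshold,
                 peak_min_distance = peak_min_distance,
                 pseudo_radius = as.integer(pseudo_radius),
                 n_target_images_per_cycle =
                   as.integer(n_target_images_per_cycle),
                 source_fraction = source_fraction),
            class = "adapt_config")
}

# label 8-connected components of a logical matrix by BFS; intended
# for sparse masks (peak candidates).
label_components8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask, arr.ind = TRUE)
  nxt <- 0L
  for (k in seq_len(nrow(idx))) {
    y <- idx[k, 1]; x <- idx[k, 2]
    if (lab[y, x] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(y, x))
    lab[y, x] <- nxt
    while (length(queue)) {
      p <- queue[[1L]]
      queue <- queue[-1L]
      for (dy in -1:1) for (dx in -1:1) {
        ny <- p[1] + dy; nx <- p[2] + dx
        if (ny >= 1L && ny <= nrow(mask) && nx >= 1L && nx <= ncol(mask) &&
            mask[ny, nx] && lab[ny, nx] == 0L) {
          lab[ny, nx] <- nxt
          queue[[length(queue) + 1L]] <- c(ny, nx)
        }
      }
    }
  }
  lab
}

# value of the 8-neighbourhood maximum at every pixel (border-padded
# with -Inf).
neighbour_max <- function(v) {
  H <- nrow(v); W <- ncol(v)
  pad <- matrix(-Inf, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- v
  out <- matrix(-Inf, H, W)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    out <- pmax(out, pad[(2:(H + 1L)) + dy, (2:(W + 1L)) + dx])
  }
  out
}

#' Detect local peaks in a confidence heatmap
#'
#' A peak is a pixel at or above `threshold` with no strictly greater
#' 8-neighbour. A flat plateau of equal-valued candidate pixels
#' contributes a single peak: the plateau pixel closest to the plateau
#' centroid (ties broken by smallest row, then column). Peaks are then
#' accepted greedily by descending value; any candidate closer than
#' `min_distance` (Euclidean) to an already accepted peak is
#' suppressed.
#'
#' @param heatmap H x W matrix of values (typically in \[0, 1\]).
#' @param threshold Minimum peak value (default 0.2).
#' @param min_distance Minimum distance between returned peaks in px
#'   (default 5).
#' @return A [detection_set()]; confidences are the heatmap values at
#'   the peaks. Coordinates are 0-based (row, col).
#' @export
find_peaks <- function(heatmap, threshold = 0.2, min_distance = 5) {
  v <- unclass(as.matrix(heatmap))
  cand <- v >= threshold & v >= neighbour_max(v)
  if (!any(cand)) return(detection_set(matrix(numeric(0), 0, 2)))
  # plateau handling: adjacent candidates always share a value, so
  # 8-connected components of the candidate mask are plateaus
  lab <- label_components8(cand)
  reps <- lapply(seq_len(max(lab)), function(l) {
    idx <- which(lab == l, arr.ind = TRUE)
    cen <- colMeans(idx)
    d2 <- (idx[, 1] - cen[1])^2 + (idx[, 2] - cen[2])^2
    idx[order(d2, idx[, 1], idx[, 2])[1L], ]
  })
  reps <- do.call(rbind, reps)
  vals <- v[reps]
  ord <- order(-vals, reps[, 1], reps[, 2])
  reps <- reps[ord, , drop = FALSE]
  vals <- vals[ord]
  kept <- matrix(numeric(0), 0, 2)
  kv <- numeric(0)
  for (i in seq_len(nrow(reps))) {
    p <- reps[i, ]
    if (nrow(kept) == 0L ||
        min(sqrt((kept[, 1] - p[1])^2 + (kept[, 2] - p[2])^2)) >=
          min_distance) {
      kept <- rbind(kept, p)
      kv <- c(kv, vals[i])
    }
  }
  detection_set(kept - 1, pmin(1, pmax(0, kv)))  # 1-based -> 0-based
}

#' Auto-label target-domain images with the current detector
#'
#' Predicts a heatmap for each triplet, extracts peaks, and dilates
#' each peak point into a radius-`pseudo_radius` disk (plain union of
#' disks — unlike manual target masks, pseudo disks are not shrunk
#' when they touch). Images in which no peak survives still yield an
#' (all-background) training pair.
#'
#' @param detector A trained `cell_detector`.
#' @param triplets List of [plane_triplet()]s.
#' @param cfg An [adapt_config()].
#' @return List of [training_pair()]s whose annotations carry
#'   `provenance = "pseudo"`; attribute `n_pseudo_cells` holds the
#'   total peak count.
#' @export
autolabel <- function(detector, triplets, cfg = adapt_config()) {
  stopifnot(inherits(detector, "cell_detector"))
  total <- 0L
  pairs <- lapply(triplets, function(tr) {
    h <- predict_heatmap(detector, tr)
    det <- find_peaks(h, cfg$peak_threshold, cfg$peak_min_distance)
    shape <- dim(tr$channels)[1:2]
    mask <- paint_disks(det$points, rep(cfg$pseudo_radius, nrow(det$points)),
                        shape)
    total <<- total + nrow(det$points)
    training_pair(tr, mask,
                  annotation_set(det$points, shape, "pseudo"))
  })
  attr(pairs, "n_pseudo_cells") <- total
  pairs
}

#' Iterative unsupervised domain adaptation
#'
#' Adapts a source-trained detector to an unseen target domain without
#' a single target annotation. Each of the `n_cycles` cycles: (1)
#' samples `n_target_images_per_cycle` images from the unlabeled
#' target pool (with replacement only if the pool is smaller, which is
#' logged in the history); (2) auto-labels them with the *current*
#' weights; (3) assembles a training pool with `source_fraction`
#' annotated source patches and the rest pseudo-labeled target
#' patches; (4) trains `epochs_per_cycle` epochs, restarting the
#' learning-rate ladder at `schedule$lr0` and halving it each cycle
#' while switching patch size — mirroring the supervised schedule.
#' Validation during adaptation uses held-out *annotated source*
#' patches only: pseudo-labels cannot play ground truth, since a
#' detector collapsing to all-background scores well against its own
#' empty pseudo-masks. Each cycle's best-validating weights — the
#' cycle's starting weights, if nothing improved — carry into the next
#' cycle. Source patches keep their manual masks throughout;
#' pseudo-labels never overwrite them.
#'
#' @param detector A source-trained `cell_detector`.
#' @param source_pool List of annotated [training_pair()]s (source
#'   domain, full images).
#' @param target_images List of [plane_triplet()]s from the target
#'   domain; must exclude any held-out test images.
#' @param cfg An [adapt_config()].
#' @param schedule A [train_schedule()] (its lr0/decay/momentum/batch
#'   size/patch sizes are reused).
#' @param seed Integer seed.
#' @return List with `detector` (adapted), and `history`: one row per
#'   cycle (cycle, lr, patch_size, pseudo_cell_count,
#'   n_source_patches, n_pseudo_patches, resampled, train_loss,
#'   val_loss).
#' @export
adapt_iteratively <- function(detector, source_pool, target_images,
                              cfg = adapt_config(),
                              schedule = train_schedule(), seed = 1L) {
  stopifnot(inherits(detector, "cell_detector"),
            length(source_pool) >= 1L, length(target_images) >= 1L,
            all(vapply(source_pool, inherits, logical(1), "training_pair")))
  params <- detector$params
  velocity <- lapply(params, function(p) list(W = p$W * 0, b = p$b * 0))
  history <- NULL
  aug <- augmentation_params()
  for (cyc in seq_len(cfg$n_cycles)) {
    set.seed(derive_seed(seed, 500L + cyc))
    replace <- length(target_images) < cfg$n_target_images_per_cycle
    pick <- sample.int(length(target_images),
                       cfg$n_target_images_per_cycle, replace = replace)
    detector$params <- params
    pseudo_pairs <- autolabel(detector, target_images[pick], cfg)
    n_pseudo_cells <- attr(pseudo_pairs, "n_pseudo_cells")

    ps <- schedule$patch_sizes[(cyc - 1L) %% length(schedule$patch_sizes) + 1L]
    lr <- schedule$lr0 * schedule$lr_decay^(cyc - 1L)
    pseudo_patches <- crop_patches(pseudo_pairs, ps,
                                   schedule$patches_per_image)
    # source_fraction of the training pool comes from annotated source
    # patches; a further quarter-sized set of source patches is held
    # out as validation. Pseudo-labels cannot serve as validation
    # ground truth: a detector that collapses to predicting background
    # looks *good* against its own near-empty pseudo-masks, so
    # validating on manual annotations is what lets the best-weights
    # rule roll back a cycle that went off the rails.
    n_src <- round(length(pseudo_patches) * cfg$source_fraction /
                     (1 - cfg$source_fraction))
    n_val <- max(1L, round(0.25 * (n_src + length(pseudo_patches))))
    src_imgs <- sample.int(length(source_pool), n_src + n_val,
                           replace = TRUE)
    source_patches <- lapply(src_imgs, function(i)
      crop_patch(source_pool[[i]], ps))
    val_patches <- source_patches[seq_len(n_val)]
    source_patches <- source_patches[-seq_len(n_val)]
    pool <- c(source_patches, pseudo_patches)
    # seed the best-weights rule with the incoming weights: a cycle
    # whose every epoch validates worse than its starting point is
    # rolled back entirely
    inc_val <- cpp_unet_mean_loss(unet_spec(detector$config), params,
                                  lapply(val_patches, `[[`, "x"),
                                  lapply(val_patches, `[[`, "y"))
    r <- run_epochs(detector$config, params, velocity, pool, val_patches,
                    cfg$epochs_per_cycle, lr, schedule$momentum,
                    schedule$batch_size, aug,
                    best = list(params = params, val_loss = inc_val))
    params <- r$best$params     # best-of-cycle carries forward
    velocity <- r$velocity
    history <- rbind(history, data.frame(
      cycle = cyc, lr = lr, patch_size = ps,
      pseudo_cell_count = n_pseudo_cells,
      n_source_patches = length(source_patches),
      n_pseudo_patches = length(pseudo_patches),
      resampled = replace,
      train_loss = utils::tail(r$history$train_loss, 1),
      val_loss = r$best$val_loss))
  }
  detector$params <- params
  detector$trained <- TRUE
  list(detector = detector, history = history)
}
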