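#' Training schedule
#'
#' The supervised schedule: pixel-mean binary cross-entropy, SGD with
#' Nesterov momentum 0.8, batch size 5, learning rate 0.1 halved after
#' every 10 epochs, 60 epochs in total, one quarter of the training set
#' set aside for validation, and the input patch size switched at every
#' 10-epoch cycle boundary (the network is fully convolutional, so the
#' patch size is free; switching it varies how much border each patch
#' contributes). Fresh random patches are cropped from the training
#' images at every cycle.
#'
#' @param total_epochs Total epochs (default 60); must be divisible by
#'   `cycle_length`.
#' @param cycle_length Epochs per cycle (default 10).
#' @param lr0 Initial learning rate (default 0.1).
#' @param lr_decay Multiplicative decay per cycle (default 0.5).
#' @param momentum Nesterov momentum (default 0.8).
#' @param batch_size Minibatch size (default 5).
#' @param val_fraction Fraction of the training set held out for
#'   validation (default 0.25).
#' @param patch_sizes Integer vector of square patch sizes cycled per
#'   10-epoch block; every size must be divisible by `2^depth` of the
#'   detector. Default is the desk-scale cycle `c(64, 96, 48, 80, 64,
#'   96)`; pass e.g. `c(256, 384, 192, 320, 256, 384)` for full-size
#'   imagery.
#' @param patches_per_image Random crops taken from each training image
#'   per cycle (default 4).
#' @return An object of class `train_schedule`.
#' @export
train_schedule <- function(total_epochs = 60L, cycle_length = 10L,
                           lr0 = 0.1, lr_decay = 0.5, momentum = 0.8,
                           batch_size = 5L, val_fraction = 0.25,
                           patch_sizes = c(64L, 96L, 48L, 80L, 64L, 96L),
                           patches_per_image = 4L) {
  total_epochs <- as.integer(total_epochs)
  cycle_length <- as.integer(cycle_length)
  if (total_epochs %% cycle_length != 0L)
    stop("total_epochs must be divisible by cycle_length", call. = FALSE)
  stopifnot(lr0 > 0, lr_decay > 0, momentum >= 0, momentum < 1,
            batch_size >= 1, val_fraction > 0, val_fraction < 1,
            all(patch_sizes >= 8))
  structure(list(total_epochs = total_epochs, cycle_length = cycle_length,
                 lr0 = lr0, lr_decay = lr_decay, momentum = momentum,
                 batch_size = as.integer(batch_size),
                 val_fraction = val_fraction,
                 patch_sizes = as.integer(patch_sizes),
                 patches_per_image = as.integer(patches_per_image)),
            class = "train_schedule")
}

#' Learning rate at a given epoch
#'
#' `lr0 * lr_decay^floor(epoch / cycle_length)`: 0.1 at epoch 0,
#' halved after every 10 epochs, 0.003125 at epoch 59 under the
#' default schedule.
#'
#' @param schedule A [train_schedule()].
#' @param epoch 0-based epoch index in `[0, total_epochs)`.
#' @return The learning rate.
#' @export
lr_at_epoch <- function(schedule, epoch) {
  stopifnot(inherits(schedule, "train_schedule"))
  if (any(epoch < 0 | epoch >= schedule$total_epochs))
    stop("epoch out of range", call. = FALSE)
  schedule$lr0 * schedule$lr_decay^(epoch %/% schedule$cycle_length)
}

#' Augmentation parameters
#'
#' Geometric transforms (right-angle rotations, flips) are applied
#' jointly to image and target mask; they are pixel permutations, so
#' the mask stays binary with no interpolation policy. Photometric
#' transforms (additive intensity shift, Gaussian noise) touch the
#' image only. Translation is realized as crop-offset jitter at patch
#' extraction time rather than as a resampling transform.
#'
#' @param rotate Allow 0/90/180/270-degree rotations (square patches
#'   only)? Default `TRUE`.
#' @param flip Allow horizontal/vertical flips? Default `TRUE`.
#' @param intensity_shift Max additive shift as a fraction of the
#'   patch's dynamic range; uniform in `+/-` this value. Default 0.1.
#' @param noise_sigma Additive Gaussian noise, standard deviation as a
#'   fraction of the patch's dynamic range (default 0.02).
#' @return An object of class `augmentation_params`.
#' @export
augmentation_params <- function(rotate = TRUE, flip = TRUE,
                                intensity_shift = 0.1, noise_sigma = 0.02) {
  structure(list(rotate = isTRUE(rotate), flip = isTRUE(flip),
                 intensity_shift = intensity_shift,
                 noise_sigma = noise_sigma),
            class = "augmentation_params")
}

rot90k <- function(m, k) {
  k <- k %% 4L
  for (i in seq_len(k)) m <- t(m)[ncol(m):1, , drop = FALSE]
  m
}

#' Randomly augment an image/mask patch pair
#'
#' Draws from R's RNG; seed externally for reproducibility. With all
#' magnitudes zero and rotations/flips disabled this is the identity.
#'
#' @param image H x W x C array.
#' @param mask H x W binary matrix; receives only the geometric
#'   transforms.
#' @param params An [augmentation_params()].
#' @return List with augmented `image` and `mask`.
#' @export
augment <- function(image, mask, params = augmentation_params()) {
  stopifnot(length(dim(image)) == 3L, all(dim(image)[1:2] == dim(mask)))
  k <- if (params$rotate && dim(mask)[1] == dim(mask)[2])
    sample(0:3, 1L) else 0L
  fh <- params$flip && stats::runif(1) < 0.5
  fv <- params$flip && stats::runif(1) < 0.5
  geom <- function(m) {
    m <- rot90k(m, k)
    if (fh) m <- m[, ncol(m):1, drop = FALSE]
    if (fv) m <- m[nrow(m):1, , drop = FALSE]
    m
  }
  img <- array(0, c(dim(geom(image[, , 1])), dim(image)[3]))
  for (i in seq_len(dim(image)[3])) img[, , i] <- geom(image[, , i])
  mask <- geom(mask)
  rng <- diff(range(img))  # photometric magnitudes scale with dynamic range
  if (params$intensity_shift > 0)
    img <- img + stats::runif(1, -params$intensity_shift,
                              params$intensity_shift) * rng
  if (params$noise_sigma > 0)
    img <- img + array(stats::rnorm(length(img),
                                    sd = params$noise_sigma * rng),
                       dim(img))
  list(image = img, mask = mask)
}

#' Bundle a plane triplet with its training target
#'
#' @param triplet A [plane_triplet()].
#' @param mask A `target_mask` (or plain binary matrix).
#' @param ann Optional [annotation_set()] the mask was built from;
#'   required by [rescale_dataset()].
#' @return An object of class `training_pair`.
#' @export
training_pair <- function(triplet, mask, ann = NULL) {
  m <- if (inherits(mask, "target_mask")) mask$mask else mask
  stopifnot(inherits(triplet, "plane_triplet"),
            all(dim(triplet$channels)[1:2] == dim(m)))
  structure(list(triplet = triplet, mask = m, ann = ann),
            class = "training_pair")
}

#' Build training pairs from synthetic samples
#'
#' Convenience wrapper: selects the in-focus plane triplet of each
#' sample and rasterizes its ground truth into a target mask.
#'
#' @param samples List of `synthetic_sample` objects.
#' @param max_radius Target-disk radius (default 8).
#' @param start_index Triplet start plane; default each stack's
#'   in-focus plane.
#' @return List of [training_pair()]s.
#' @export
training_pairs_from_samples <- function(samples, max_radius = 8L,
                                        start_index = NULL) {
  lapply(samples, function(s) {
    si <- if (is.null(start_index)) s$stack$in_focus_index else start_index
    training_pair(select_triplet(s$stack, si),
                  make_target_mask(s$truth, max_radius), s$truth)
  })
}

#' Double a training set by rescaling
#'
#' Appends a copy of every pair resized to `factor` (default 0.75) of
#' its original size, with target masks rebuilt at the proportionally
#' reduced radius — exposing the detector to smaller cells than the
#' source line provides.
#'
#' @param pairs List of [training_pair()]s carrying annotations.
#' @param factor Scale factor in (0, 1].
#' @param max_radius Original mask radius (default 8).
#' @return List of length `2 * length(pairs)`.
#' @export
rescale_dataset <- function(pairs, factor = 0.75, max_radius = 8L) {
  extra <- lapply(pairs, function(p) {
    if (is.null(p$ann))
      stop("rescale_dataset needs pairs with annotations", call. = FALSE)
    r <- rescale_pair(p$triplet, p$ann, factor, max_radius)
    training_pair(r$triplet, make_target_mask(r$ann, r$new_max_radius),
                  r$ann)
  })
  c(pairs, extra)
}

# Random square crop of a training pair; offset jitter doubles as the
# translation augmentation.
crop_patch <- function(pair, size) {
  d <- dim(pair$triplet$channels)
  if (size > d[1] || size > d[2])
    stop(sprintf("patch size %d exceeds image %dx%d", size, d[1], d[2]),
         call. = FALSE)
  y0 <- sample.int(d[1] - size + 1L, 1L)
  x0 <- sample.int(d[2] - size + 1L, 1L)
  list(x = pair$triplet$channels[y0:(y0 + size - 1L),
                                 x0:(x0 + size - 1L), , drop = FALSE],
       y = pair$mask[y0:(y0 + size - 1L), x0:(x0 + size - 1L)] * 1)
}

crop_patches <- function(pairs, size, n_per_image) {
  out <- list()
  for (p in pairs)
    for (i in seq_len(n_per_image))
      out[[length(out) + 1L]] <- crop_patch(p, size)
  out
}

# Core loop shared by supervised training and each adaptation cycle:
# train `epochs` epochs at a fixed lr/patch size on pre-cropped
# train/val patches, augmenting train patches freshly every epoch.
# Returns updated params/velocity, per-epoch losses, and the params
# with the lowest validation loss seen (best-checkpoint rule).
run_epochs <- function(config, params, velocity, train_patches, val_patches,
                       epochs, lr, momentum, batch_size, aug,
                       best = NULL) {
  spec <- unet_spec(config)
  Xv <- lapply(val_patches, `[[`, "x")
  Yv <- lapply(val_patches, `[[`, "y")
  hist <- data.frame(train_loss = numeric(0), val_loss = numeric(0),
                     checkpointed = logical(0))
  for (e in seq_len(epochs)) {
    augd <- lapply(train_patches, function(p) {
      a <- augment(p$x, p$y, aug)
      list(x = a$image, y = a$mask)
    })
    ord <- sample.int(length(augd)) - 1L
    r <- cpp_unet_train_epoch(spec, params, velocity,
                              lapply(augd, `[[`, "x"),
                              lapply(augd, `[[`, "y"),
                              ord, batch_size, lr, momentum)
    params <- r$params
    velocity <- r$velocity
    vl <- cpp_unet_mean_loss(spec, params, Xv, Yv)
    ck <- is.null(best) || vl < best$val_loss
    if (ck) best <- list(params = params, val_loss = vl)
    hist <- rbind(hist, data.frame(train_loss = r$train_loss,
                                   val_loss = vl, checkpointed = ck))
  }
  list(params = params, velocity = velocity, best = best, history = hist)
}

#' Supervised training of the detector
#'
#' Runs the full schedule: at each 10-epoch cycle the patch size
#' switches and fresh random patches are cropped from the training
#' images; every epoch re-augments the patches, shuffles, and performs
#' minibatch SGD with Nesterov momentum on pixel-mean binary
#' cross-entropy. One quarter of the images is set aside for
#' validation (split at the image level when there are at least four
#' images, at the patch level otherwise), and the returned weights are
#' those of the epoch with the lowest validation loss.
#'
#' @param detector A `cell_detector` (freshly built or pre-trained).
#' @param dataset List of [training_pair()]s (full images).
#' @param schedule A [train_schedule()].
#' @param aug An [augmentation_params()].
#' @param seed Integer seed governing the split, crops, augmentation
#'   and shuffling.
#' @return List with `detector` (best-validation weights), `history`
#'   (one row per epoch: epoch, cycle, lr, patch_size, train_loss,
#'   val_loss, checkpointed), and `val_images` (indices held out).
#' @export
train_supervised <- function(detector, dataset, schedule = train_schedule(),
                             aug = augmentation_params(), seed = 1L) {
  stopifnot(inherits(detector, "cell_detector"), length(dataset) >= 1L,
            all(vapply(dataset, inherits, logical(1), "training_pair")))
  div <- 2^detector$config$depth
  if (any(schedule$patch_sizes %% div != 0L))
    stop("all patch sizes must be divisible by 2^depth", call. = FALSE)
  set.seed(derive_seed(seed, 0L))
  n <- length(dataset)
  n_val_img <- floor(schedule$val_fraction * n)
  if (n_val_img >= 1L) {
    val_idx <- sort(sample.int(n, n_val_img))
    train_set <- dataset[-val_idx]
    val_set <- dataset[val_idx]
  } else {
    val_idx <- integer(0)
    train_set <- dataset
    val_set <- dataset  # patch-level split below
  }
  params <- detector$params
  velocity <- lapply(params, function(p)
    list(W = p$W * 0, b = p$b * 0))
  best <- NULL
  n_cycles <- schedule$total_epochs %/% schedule$cycle_length
  history <- NULL
  for (cyc in seq_len(n_cycles)) {
    ps <- schedule$patch_sizes[(cyc - 1L) %% length(schedule$patch_sizes) + 1L]
    lr <- lr_at_epoch(schedule, (cyc - 1L) * schedule$cycle_length)
    set.seed(derive_seed(seed, cyc))
    tp <- crop_patches(train_set, ps, schedule$patches_per_image)
    vp <- crop_patches(val_set, ps, schedule$patches_per_image)
    if (length(val_idx) == 0L) {  # patch-level split for tiny datasets
      nv <- max(1L, floor(schedule$val_fraction * length(tp)))
      vi <- sample.int(length(tp), nv)
      vp <- tp[vi]
      tp <- tp[-vi]
    }
    r <- run_epochs(detector$config, params, velocity, tp, vp,
                    schedule$cycle_length, lr, schedule$momentum,
                    schedule$batch_size, aug, best)
    params <- r$params
    velocity <- r$velocity
    best <- r$best
    h <- r$history
    h$cycle <- cyc
    h$lr <- lr
    h$patch_size <- ps
    history <- rbind(history, h)
  }
  history$epoch <- seq_len(nrow(history))
  detector$params <- best$params
  detector$trained <- TRUE
  list(detector = detector,
       history = history[, c("epoch", "cycle", "lr", "patch_size",
                             "train_loss", "val_loss", "checkpointed")],
       val_images = val_idx)
}
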