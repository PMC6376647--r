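test_that("learning rate follows the halving ladder exactly", {
  sch <- train_schedule()
  expect_identical(lr_at_epoch(sch, 0), 0.1)
  expect_identical(lr_at_epoch(sch, 9), 0.1)
  expect_identical(lr_at_epoch(sch, 10), 0.05)
  expect_identical(lr_at_epoch(sch, 59), 0.1 * 0.5^5)  # 0.003125
  expect_equal(lr_at_epoch(sch, 0:59),
               0.1 * 0.5^(rep(0:5, each = 10)))
  expect_error(lr_at_epoch(sch, 60), "out of range")
  expect_error(lr_at_epoch(sch, -1), "out of range")
  expect_error(train_schedule(total_epochs = 55), "divisible")
})

test_that("augmentation preserves binary masks and applies joint geometry", {
  set.seed(21)
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  ann <- annotation_set(rbind(c(4, 4)), c(16L, 16L))
  mask <- make_target_mask(ann, 2)$mask * 1

  # all transforms off: exact identity
  idp <- augmentation_params(rotate = FALSE, flip = FALSE,
                             intensity_shift = 0, noise_sigma = 0)
  a0 <- augment(img, mask, idp)
  expect_identical(a0$image, img)
  expect_identical(a0$mask, mask)

  # geometric transforms permute pixels: mask stays binary with the
  # same foreground count; image histogram is preserved
  geo <- augmentation_params(intensity_shift = 0, noise_sigma = 0)
  for (i in 1:10) {
    a <- augment(img, mask, geo)
    expect_true(all(a$mask %in% c(0, 1)))
    expect_equal(sum(a$mask), sum(mask))
    expect_equal(sort(as.vector(a$image)), sort(as.vector(img)))
  }

  # photometric transforms never touch the mask
  pho <- augmentation_params(rotate = FALSE, flip = FALSE,
                             intensity_shift = 0.1, noise_sigma = 0.05)
  a2 <- augment(img, mask, pho)
  expect_identical(a2$mask, mask)
  expect_false(identical(a2$image, img))
})

test_that("training learns on a small synthetic set and checkpoints the best epoch", {
  pairs <- training_pairs_from_samples(
    lapply(1:4, function(i) simulate_sample(
      domain_preset("sourcelike", n_cells = c(4L, 7L)),
      image_shape = c(64L, 64L), seed = 300 + i)),
    max_radius = 6)
  set.seed(31)
  det <- build_detector(model_config(depth = 3, base_filters = 4))
  sch <- train_schedule(total_epochs = 10L, cycle_length = 5L,
                        patch_sizes = c(48L, 64L), patches_per_image = 3L)
  r <- train_supervised(det, pairs, sch, seed = 31)

  expect_lte(nrow(r$history), 10L)
  expect_lt(tail(r$history$val_loss, 1), r$history$val_loss[1])
  # returned weights come from the minimum-validation-loss epoch
  best_epoch <- which.min(r$history$val_loss)
  expect_true(r$history$checkpointed[best_epoch])
  expect_true(r$detector$trained)
  # patch size switched at the cycle boundary
  expect_equal(unique(r$history$patch_size[r$history$cycle == 1]), 48L)
  expect_equal(unique(r$history$patch_size[r$history$cycle == 2]), 64L)
  expect_equal(unique(r$history$lr), c(0.1, 0.05))
})

test_that("validation split is disjoint and reproducible from the seed", {
  pairs <- training_pairs_from_samples(
    lapply(1:8, function(i) simulate_sample(
      domain_preset("sourcelike", n_cells = c(4L, 7L)),
      image_shape = c(64L, 64L), seed = 400 + i)),
    max_radius = 6)
  set.seed(1)
  det <- build_detector(model_config(depth = 3, base_filters = 2))
  sch <- train_schedule(total_epochs = 5L, cycle_length = 5L,
                        patch_sizes = 32L, patches_per_image = 1L)
  r1 <- train_supervised(det, pairs, sch, seed = 77)
  r2 <- train_supervised(det, pairs, sch, seed = 77)
  expect_identical(r1$val_images, r2$val_images)
  expect_equal(length(r1$val_images), 2L)  # quarter of 8
  expect_identical(r1$history, r2$history) # whole run reproducible
  r3 <- train_supervised(det, pairs, sch, seed = 78)
  expect_false(identical(r3$history$val_loss, r1$history$val_loss))
})

test_that("rescale_dataset doubles the training set", {
  pairs <- training_pairs_from_samples(
    lapply(1:2, function(i) simulate_sample(
      domain_preset("sourcelike", n_cells = c(4L, 7L)),
      image_shape = c(64L, 64L), seed = 500 + i)),
    max_radius = 8)
  doubled <- rescale_dataset(pairs, 0.75, max_radius = 8)
  expect_length(doubled, 4L)
  expect_equal(dim(doubled[[3]]$triplet$channels)[1:2], c(48, 48))
  # rescaled copies keep one annotation per surviving cell
  expect_lte(n_cells(doubled[[3]]$ann), n_cells(pairs[[1]]$ann))
})

test_that("patches larger than the training images are rejected", {
  pairs <- training_pairs_from_samples(
    list(simulate_sample(domain_preset("sourcelike", n_cells = c(4L, 7L)),
                         image_shape = c(64L, 64L), seed = 1)),
    max_radius = 6)
  set.seed(1)
  det <- build_detector(model_config(depth = 3, base_filters = 2))
  sch <- train_schedule(total_epochs = 5L, cycle_length = 5L,
                        patch_sizes = 128L, patches_per_image = 1L)
  expect_error(train_supervised(det, pairs, sch, seed = 1), "exceeds image")
})
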