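test_that("simulation is reproducible and annotations match rendered cells", {
  p <- domain_preset("sourcelike")
  s1 <- simulate_sample(p, seed = 101)
  s2 <- simulate_sample(p, seed = 101)
  expect_identical(s1$stack$planes, s2$stack$planes)
  expect_identical(s1$truth$points, s2$truth$points)
  expect_true(n_cells(s1$truth) >= p$n_cells[1] &&
              n_cells(s1$truth) <= p$n_cells[2])

  s3 <- simulate_sample(p, seed = 102)
  expect_false(identical(s1$stack$planes, s3$stack$planes))
})

test_that("an empty preset renders background plus noise only", {
  p <- domain_preset("sourcelike", n_cells = c(0L, 0L))
  s <- simulate_sample(p, seed = 5)
  expect_equal(n_cells(s$truth), 0L)
  expect_equal(mean(s$stack$planes), p$background_level, tolerance = 0.01)
  expect_equal(sd(s$stack$planes), p$noise_sigma, tolerance = 0.005)
})

test_that("cell contrast inverts across the focus plane", {
  p <- domain_preset("sourcelike", noise_sigma = 0)
  s <- simulate_sample(p, n_planes = 5L, seed = 7)
  focus <- s$stack$in_focus_index
  for (i in seq_len(n_cells(s$truth))) {
    pt <- s$truth$points[i, ] + 1
    above <- s$stack$planes[pt[1], pt[2], focus + 2] - p$background_level
    below <- s$stack$planes[pt[1], pt[2], focus - 2] - p$background_level
    expect_lt(above * below, 0)  # opposite signs
  }
  # the in-focus plane carries (near) zero cell signal by construction
  centre <- s$stack$planes[, , focus]
  expect_equal(max(abs(centre - p$background_level)), 0, tolerance = 1e-9)
})

test_that("defocus blur grows away from focus", {
  p <- domain_preset("sourcelike", n_cells = c(1L, 1L), noise_sigma = 0,
                     min_separation = 2)
  s <- simulate_sample(p, n_planes = 5L, seed = 11)
  pt <- s$truth$points[1, ]
  # measure blob width as foreground spread at half-max in two planes
  spread <- function(plane) {
    dev <- abs(s$stack$planes[, , plane] - p$background_level)
    sum(dev > max(dev) / 2)
  }
  expect_gt(spread(5), spread(4))  # farther from focus -> wider blob
})

test_that("clustered placement concentrates cells relative to uniform", {
  # clustering shows up as a smaller typical pairwise distance (cells
  # share clusters) even though the hard minimum separation is larger
  pd <- function(s, seed) median(dist(simulate_sample(s, seed = seed)$truth$points))
  src <- median(vapply(13:15, function(i) pd(domain_preset("sourcelike"), i),
                       numeric(1)))
  tgt <- median(vapply(13:15, function(i) pd(domain_preset("targetlike"), i),
                       numeric(1)))
  expect_lt(tgt, src)
})

test_that("make_domain_pair produces disjoint annotated splits", {
  pair <- make_domain_pair(
    domain_preset("sourcelike", n_cells = c(3L, 5L)),
    domain_preset("targetlike", n_cells = c(3L, 5L), cluster_sd = 6),
    n_train = 3L, n_target = 2L, n_test = 2L,
    image_shape = c(64L, 64L), seed = 3)
  expect_length(pair$source_train, 3L)
  expect_length(pair$target_pool, 2L)
  expect_length(pair$source_test, 2L)
  expect_length(pair$target_test, 2L)
  # test images must differ from pool/training images
  key <- function(s) paste(s$truth$points, collapse = ",")
  expect_false(any(vapply(pair$target_test, key, "") %in%
                   vapply(pair$target_pool, key, "")))
  expect_false(any(vapply(pair$source_test, key, "") %in%
                   vapply(pair$source_train, key, "")))
  # identical presets are refused
  expect_error(make_domain_pair(domain_preset("sourcelike"),
                                domain_preset("sourcelike")),
               "differ")
})

test_that("requests impossible at the minimum separation are rejected", {
  p <- domain_preset("sourcelike", n_cells = c(300L, 300L))
  expect_error(simulate_sample(p, image_shape = c(48L, 48L), seed = 1),
               "too small")
})

test_that("seed derivation is deterministic and stage-sensitive", {
  expect_identical(derive_seed(1L, 1L), derive_seed(1L, 1L))
  expect_false(derive_seed(1L, 1L) == derive_seed(1L, 2L))
  expect_false(derive_seed(1L, 1L) == derive_seed(2L, 1L))
  s <- vapply(1:1000, function(i) derive_seed(7L, i), integer(1))
  expect_true(all(s >= 1 & s < 2^31))
})
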