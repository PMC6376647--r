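# Synthetic through-focus stacks. Cells are rendered as radially
# symmetric blobs whose signed amplitude crosses zero at the in-focus
# plane and inverts across it (bright on one side of focus, dark on
# the other), with blur growing with defocus — the qualitative
# through-focus behaviour the detector exploits. This is a
# phenomenological appearance model, not an optics simulation.

#' Domain presets for the synthetic stack generator
#'
#' A "domain" is a cell line with its characteristic appearance. The
#' two built-in presets mirror the two appearance classes the method is
#' designed around: `"sourcelike"` — sparse, well-separated,
#' high-contrast cells (the annotated training line); `"targetlike"` —
#' dense clustered populations of smaller, low-contrast cells (the
#' unseen line that motivates domain adaptation: larger cells at a
#' fraction of the source contrast, packed into clusters so tightly
#' that neighbours touch and little background remains between them).
#'
#' @param name `"sourcelike"` or `"targetlike"`, or `"custom"` with
#'   fields supplied via `...`.
#' @param ... Overrides for individual preset fields: `cell_radius_px`
#'   (mean), `cell_radius_sd`, `contrast` (peak amplitude relative to a
#'   unit-scaled background), `defocus_sign` (+1 bright above focus, -1
#'   inverted), `n_cells` (length-2 range), `clustering` (`"none"` or
#'   `"clustered"`), `cluster_sd` (px), `cells_per_cluster` (mean),
#'   `min_separation` (px), `background_level`, `noise_sigma`.
#' @return An object of class `domain_preset`.
#' @export
domain_preset <- function(name = c("sourcelike", "targetlike", "custom"),
                          ...) {
  name <- match.arg(name)
  base <- switch(name,
    sourcelike = list(cell_radius_px = 5, cell_radius_sd = 0.8,
                      contrast = 0.45, defocus_sign = 1,
                      n_cells = c(10L, 20L), clustering = "none",
                      cluster_sd = NA_real_, cells_per_cluster = NA_real_,
                      min_separation = 14, background_level = 0.5,
                      noise_sigma = 0.002),
    targetlike = list(cell_radius_px = 8, cell_radius_sd = 1,
                      contrast = 0.06, defocus_sign = 1,
                      n_cells = c(8L, 12L), clustering = "clustered",
                      cluster_sd = 10, cells_per_cluster = 4,
                      min_separation = 17, background_level = 0.5,
                      noise_sigma = 0.002),
    custom = list(cell_radius_px = 4, cell_radius_sd = 0.5,
                  contrast = 0.3, defocus_sign = 1,
                  n_cells = c(10L, 20L), clustering = "none",
                  cluster_sd = NA_real_, cells_per_cluster = NA_real_,
                  min_separation = 8, background_level = 0.5,
                  noise_sigma = 0.002))
  over <- list(...)
  bad <- setdiff(names(over), names(base))
  if (length(bad)) stop("unknown preset field(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  base[names(over)] <- over
  stopifnot(base$contrast > 0, base$cell_radius_px >= 2)
  structure(c(list(name = name), base), class = "domain_preset")
}

#' @export
print.domain_preset <- function(x, ...) {
  cat(sprintf(
    "<domain_preset> %s: radius %g px, contrast %g, %s, %d-%d cells\n",
    x$name, x$cell_radius_px, x$contrast, x$clustering,
    x$n_cells[1], x$n_cells[2]))
  invisible(x)
}

# Place n cell centres (0-based coords) with minimum pairwise
# separation; clustered placement follows a Matern-style process:
# uniform cluster parents, Gaussian offspring around them.
place_cells <- function(preset, shape, n) {
  if (n == 0L) return(matrix(numeric(0), 0, 2))
  margin <- ceiling(preset$cell_radius_px)
  lo <- c(margin, margin)
  hi <- shape - 1 - margin
  if (any(hi < lo)) stop("image too small for the preset cell size",
                         call. = FALSE)
  pts <- matrix(numeric(0), 0, 2)
  propose <- if (identical(preset$clustering, "clustered")) {
    n_parents <- max(1L, ceiling(n / preset$cells_per_cluster))
    parents <- cbind(stats::runif(n_parents, lo[1], hi[1]),
                     stats::runif(n_parents, lo[2], hi[2]))
    function() {
      p <- parents[sample.int(nrow(parents), 1L), ]
      pmin(pmax(round(p + stats::rnorm(2, sd = preset$cluster_sd)), lo), hi)
    }
  } else {
    function() round(c(stats::runif(1, lo[1], hi[1]),
                       stats::runif(1, lo[2], hi[2])))
  }
  tries <- 0L
  while (nrow(pts) < n) {
    cand <- propose()
    ok <- nrow(pts) == 0L ||
      min(sqrt((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2)) >=
        max(2, preset$min_separation)
    if (ok) pts <- rbind(pts, cand)
    tries <- tries + 1L
    if (tries > 2000L * n)
      stop("image too small for requested cell count at minimum separation",
           call. = FALSE)
  }
  unname(pts)
}

#' Simulate a synthetic brightfield focus stack
#'
#' Renders each cell in every plane as a Gaussian-profile blob whose
#' amplitude grows linearly with signed defocus — zero at the in-focus
#' plane, brightening on one side and darkening on the other — while
#' its width grows with absolute defocus (`radius * (1 + 0.3 |p -
#' focus|)`). Additive Gaussian noise is applied last. All randomness
#' comes from R's RNG: call [set.seed()] (or pass `seed`) for
#' bit-reproducible samples.
#'
#' @param preset A [domain_preset()].
#' @param image_shape `c(height, width)` in pixels (default 128x128,
#'   the desk-scale geometry used throughout the package's tests).
#' @param n_planes Odd number of focal planes >= 3 (default 5); the
#'   centre plane is in focus.
#' @param seed Optional integer seed.
#' @return A list of class `synthetic_sample`: `stack` ([zstack()]),
#'   `truth` ([annotation_set()]), `preset`, `seed`.
#' @export
simulate_sample <- function(preset, image_shape = c(128L, 128L),
                            n_planes = 5L, seed = NULL) {
  stopifnot(inherits(preset, "domain_preset"))
  n_planes <- as.integer(n_planes)
  if (n_planes < 3L || n_planes %% 2L == 0L)
    stop("n_planes must be odd and >= 3", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  shape <- as.integer(image_shape)
  focus <- (n_planes + 1L) %/% 2L
  half_range <- (n_planes - 1) / 2
  n <- if (preset$n_cells[1] == preset$n_cells[2]) preset$n_cells[1] else
    sample(preset$n_cells[1]:preset$n_cells[2], 1L)
  pts <- place_cells(preset, shape, n)
  radii <- if (n > 0)
    pmax(2, stats::rnorm(n, preset$cell_radius_px, preset$cell_radius_sd))
  else numeric(0)
  planes <- array(preset$background_level, c(shape, n_planes))
  ygrid <- seq_len(shape[1]) - 1
  xgrid <- seq_len(shape[2]) - 1
  for (p in seq_len(n_planes)) {
    amp <- preset$contrast * preset$defocus_sign * (p - focus) / half_range
    if (amp == 0 || n == 0L) next
    img <- matrix(0, shape[1], shape[2])
    for (i in seq_len(n)) {
      w <- radii[i] * (1 + 0.3 * abs(p - focus))
      ext <- ceiling(3 * w)
      ys <- max(0, pts[i, 1] - ext):min(shape[1] - 1, pts[i, 1] + ext)
      xs <- max(0, pts[i, 2] - ext):min(shape[2] - 1, pts[i, 2] + ext)
      gy <- exp(-(ys - pts[i, 1])^2 / (2 * w^2))
      gx <- exp(-(xs - pts[i, 2])^2 / (2 * w^2))
      img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] + amp * outer(gy, gx)
    }
    planes[, , p] <- planes[, , p] + img
  }
  if (preset$noise_sigma > 0)
    planes <- planes + array(stats::rnorm(length(planes),
                                          sd = preset$noise_sigma),
                             dim(planes))
  structure(list(stack = zstack(planes, plane_spacing_um = 10,
                                in_focus_index = focus),
                 truth = annotation_set(pts, shape, "manual"),
                 preset = preset, seed = seed),
            class = "synthetic_sample")
}

#' @export
print.synthetic_sample <- function(x, ...) {
  cat(sprintf("<synthetic_sample> %s preset, %d cell(s)\n",
              x$preset$name, n_cells(x$truth)))
  print(x$stack)
  invisible(x)
}

#' Generate a paired source/target synthetic study
#'
#' Mirrors the study design the adaptation method assumes: an annotated
#' training set from the source domain, an unannotated pool of target
#' images for adaptation (truth is stored for scoring but withheld from
#' training), and held-out annotated test sets for both domains. Test
#' images are generated disjointly from all training/adaptation images,
#' so images used to measure accuracy are never available for
#' pseudo-label selection.
#'
#' @param source_preset,target_preset [domain_preset()]s; they should
#'   differ in at least one of radius, contrast, or clustering.
#' @param n_train Annotated source training images (default 12, the
#'   annotation budget the pipeline is designed around: two images per
#'   day of a six-day cultivation).
#' @param n_target Unannotated target-domain pool images (default 8).
#' @param n_test Held-out test images per domain (default 4).
#' @param image_shape,n_planes Geometry passed to [simulate_sample()].
#' @param seed Integer seed; per-image seeds are derived from it.
#' @return List of class `domain_pair` with `source_train`,
#'   `target_pool`, `source_test`, `target_test` (lists of
#'   `synthetic_sample`), and the presets.
#' @export
make_domain_pair <- function(source_preset, target_preset, n_train = 12L,
                             n_target = 8L, n_test = 4L,
                             image_shape = c(128L, 128L), n_planes = 5L,
                             seed = 1L) {
  stopifnot(inherits(source_preset, "domain_preset"),
            inherits(target_preset, "domain_preset"))
  differ <- !identical(source_preset[c("cell_radius_px", "contrast",
                                       "clustering")],
                       target_preset[c("cell_radius_px", "contrast",
                                       "clustering")])
  if (!differ)
    stop("presets must differ in radius, contrast, or clustering",
         call. = FALSE)
  gen <- function(preset, n, block) {
    lapply(seq_len(n), function(i)
      simulate_sample(preset, image_shape, n_planes,
                      seed = derive_seed(seed, block * 1000L + i)))
  }
  structure(list(source_train = gen(source_preset, n_train, 1L),
                 target_pool = gen(target_preset, n_target, 2L),
                 source_test = gen(source_preset, n_test, 3L),
                 target_test = gen(target_preset, n_test, 4L),
                 source_preset = source_preset,
                 target_preset = target_preset, seed = seed),
            class = "domain_pair")
}

#' Derive a stage seed from a global seed
#'
#' One global seed fans out to per-stage/per-image seeds through a
#' fixed affine map modulo 2^31 - 1, so each stage of a pipeline is
#' independently reproducible from the run's single seed.
#'
#' @param seed Global integer seed.
#' @param stage Integer stage index.
#' @return An integer seed in \[1, 2^31 - 2\].
#' @export
derive_seed <- function(seed, stage) {
  m <- 2147483647
  as.integer((((as.double(seed) %% m) * 48271 + as.double(stage) * 8191) %% (m - 1)) + 1)
}
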