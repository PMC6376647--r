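#' Model configuration for the reduced U-Net detector
#'
#' The detector is a symmetric encoder--decoder fully convolutional
#' network: at each of `depth` levels two 3x3 same-padding convolutions
#' with ReLU are followed by 2x2 max-pooling; the decoder mirrors this
#' with 2x2 nearest-neighbour upsampling and channel-concatenating skip
#' connections, and a 1x1 convolution with sigmoid squashing produces a
#' full-resolution confidence heatmap in \[0, 1\]. `depth = 3` is one
#' down/up level fewer than the canonical four-level U-Net: the reduced
#' architecture that detects cells as well as the full network at a
#' fraction of the parameter count.
#'
#' @param depth Number of down-sampling levels (default 3).
#' @param base_filters Number of filters at the first level; doubled at
#'   each deeper level (default 16).
#' @param in_channels Number of input channels; 3 for a focal-plane
#'   triplet.
#' @return An object of class `model_config`.
#' @export
model_config <- function(depth = 3L, base_filters = 16L, in_channels = 3L) {
  depth <- as.integer(depth)
  base_filters <- as.integer(base_filters)
  in_channels <- as.integer(in_channels)
  stopifnot(depth >= 1L, base_filters >= 1L, in_channels >= 1L)
  structure(list(depth = depth, base_filters = base_filters,
                 in_channels = in_channels),
            class = "model_config")
}

# Conv layer inventory for a given config: matrix with columns
# in_ch, out_ch, kernel, relu. Order = encoder (2 convs/level),
# bottleneck (2), decoder (2 convs/level, deep to shallow), 1x1 head.
unet_layer_spec <- function(config) {
  d <- config$depth
  f <- config$base_filters
  ch <- f * 2^(0:(d - 1))       # encoder channels per level
  cb <- f * 2^d                 # bottleneck channels
  rows <- list()
  prev <- config$in_channels
  for (i in seq_len(d)) {
    rows[[length(rows) + 1L]] <- c(prev, ch[i], 3L, 1L)
    rows[[length(rows) + 1L]] <- c(ch[i], ch[i], 3L, 1L)
    prev <- ch[i]
  }
  rows[[length(rows) + 1L]] <- c(ch[d], cb, 3L, 1L)
  rows[[length(rows) + 1L]] <- c(cb, cb, 3L, 1L)
  up <- cb
  for (i in rev(seq_len(d))) {
    rows[[length(rows) + 1L]] <- c(up + ch[i], ch[i], 3L, 1L)
    rows[[length(rows) + 1L]] <- c(ch[i], ch[i], 3L, 1L)
    up <- ch[i]
  }
  rows[[length(rows) + 1L]] <- c(ch[1], 1L, 1L, 0L)
  m <- do.call(rbind, rows)
  storage.mode(m) <- "integer"
  colnames(m) <- c("in_ch", "out_ch", "kernel", "relu")
  m
}

unet_spec <- function(config) {
  list(depth = config$depth, layers = unet_layer_spec(config))
}

#' Build a reduced U-Net cell detector
#'
#' Initializes weights with Glorot-uniform scaling (the convention of
#' the deep-learning frameworks this training schedule originated in;
#' it keeps the aggressive 0.1 initial learning rate stable). Biases
#' start at zero, so an untrained detector outputs a heatmap near 0.5
#' everywhere. Initialization draws from R's RNG, so wrap the call in
#' [set.seed()] for reproducible weights.
#'
#' @param config A [model_config()].
#' @return An object of class `cell_detector` holding the configuration
#'   and a list of layer parameters.
#' @export
build_detector <- function(config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  spec <- unet_layer_spec(config)
  params <- vector("list", nrow(spec))
  for (i in seq_len(nrow(spec))) {
    fan_in <- spec[i, "in_ch"] * spec[i, "kernel"]^2
    fan_out <- spec[i, "out_ch"] * spec[i, "kernel"]^2
    lim <- sqrt(6 / (fan_in + fan_out))
    W <- matrix(stats::runif(fan_in * spec[i, "out_ch"], -lim, lim),
                nrow = fan_in, ncol = spec[i, "out_ch"])
    params[[i]] <- list(W = W, b = numeric(spec[i, "out_ch"]))
  }
  structure(list(config = config, params = params, trained = FALSE),
            class = "cell_detector")
}

#' Number of trainable parameters of a detector
#'
#' @param detector A `cell_detector`.
#' @return Integer parameter count (weights plus biases).
#' @export
n_parameters <- function(detector) {
  stopifnot(inherits(detector, "cell_detector"))
  sum(vapply(detector$params,
             function(p) length(p$W) + length(p$b), numeric(1)))
}

#' @export
print.cell_detector <- function(x, ...) {
  cat(sprintf(
    "<cell_detector> reduced U-Net: depth %d, base filters %d, %s parameters%s\n",
    x$config$depth, x$config$base_filters,
    format(n_parameters(x), big.mark = ","),
    if (isTRUE(x$trained)) " (trained)" else " (untrained)"))
  invisible(x)
}

check_input_shape <- function(detector, h, w) {
  div <- 2^detector$config$depth
  if (h %% div != 0L || w %% div != 0L)
    stop(sprintf(
      "input %dx%d is not divisible by 2^depth = %d; pad or crop first",
      h, w, div), call. = FALSE)
}

#' Predict a cell-confidence heatmap for a plane triplet
#'
#' Deterministic for fixed weights. The network is fully convolutional:
#' any input whose height and width are divisible by `2^depth` is
#' accepted without rebuilding the detector.
#'
#' @param detector A `cell_detector`.
#' @param triplet A [plane_triplet()] (normalized, as produced by
#'   [select_triplet()]), or a plain H x W x C array.
#' @return A `heatmap` object: H x W matrix of values in \[0, 1\].
#' @export
predict_heatmap <- function(detector, triplet) {
  stopifnot(inherits(detector, "cell_detector"))
  x <- if (inherits(triplet, "plane_triplet")) triplet$channels else triplet
  stopifnot(is.array(x), length(dim(x)) == 3L)
  if (dim(x)[3] != detector$config$in_channels)
    stop(sprintf("expected %d input channels, got %d",
                 detector$config$in_channels, dim(x)[3]), call. = FALSE)
  check_input_shape(detector, dim(x)[1], dim(x)[2])
  v <- cpp_unet_predict(unet_spec(detector$config), detector$params, x)
  structure(v, class = c("heatmap", class(v)))
}

#' Save / load detector weights
#'
#' Checkpoints are versioned single files written with [saveRDS()]; the
#' model configuration travels with the weights so a checkpoint is
#' self-describing.
#'
#' @param detector A `cell_detector`.
#' @param path Checkpoint file path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored `cell_detector`.
#' @export
save_checkpoint <- function(detector, path) {
  stopifnot(inherits(detector, "cell_detector"))
  obj <- list(format = "brightcell-checkpoint", version = 1L,
              config = unclass(detector$config), params = detector$params,
              trained = isTRUE(detector$trained))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "brightcell-checkpoint"))
    stop("not a brightcell checkpoint file: ", path, call. = FALSE)
  cfg <- do.call(model_config, obj$config[c("depth", "base_filters",
                                            "in_channels")])
  structure(list(config = cfg, params = obj$params,
                 trained = isTRUE(obj$trained)),
            class = "cell_detector")
}
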