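# Two-step UNet-RCAN restoration network.
#
# Stage 1 is a residual U-Net whose encoder-decoder skip connections are
# routed through residual channel attention blocks (CABs); stage 2 is a
# residual channel attention network (RCAN) that consumes the U-Net output
# concatenated with the raw noisy input as a two-channel image.  The
# upscaling module of the original RCAN is absent because input and output
# share the same shape.

#' Network architecture configuration
#'
#' Hyperparameters of the two-step UNet-RCAN.  Defaults are the full-scale
#' settings: a depth-3 residual U-Net starting at 64 filters (doubling after
#' each of the three max-poolings), and an RCAN trunk of 3 residual groups
#' of 8 channel attention blocks with 64 filters and a 4-filter channel
#' down-scaling layer.  All convolution kernels are 3 (output layers 1),
#' LeakyReLU slope 0.3.
#'
#' @param dims 2 for planar images, 3 for volumes (all kernels become 3D).
#' @param unet_base_filters Filters of the first encoder stage.
#' @param unet_depth Number of down/up-sampling stages.
#' @param leaky_slope LeakyReLU leakage factor.
#' @param rcan_filters Filters in the RCAN trunk.
#' @param n_residual_groups Residual groups (RG) in the RCAN.
#' @param n_cab_per_group Channel attention blocks per RG.
#' @param ca_reduction_filters Filters of the channel down-scaling layer.
#' @param conv_kernel,output_kernel Kernel sizes of trunk and output convolutions.
#' @return An object of class `network_config`.
#' @export
network_config <- function(dims = 2L,
                           unet_base_filters = 64L,
                           unet_depth = 3L,
                           leaky_slope = 0.3,
                           rcan_filters = 64L,
                           n_residual_groups = 3L,
                           n_cab_per_group = 8L,
                           ca_reduction_filters = 4L,
                           conv_kernel = 3L,
                           output_kernel = 1L) {
  if (!dims %in% c(2L, 3L)) stop("dims must be 2 or 3", call. = FALSE)
  stopifnot(unet_depth >= 1L, unet_base_filters >= 1L, rcan_filters >= 1L,
            n_residual_groups >= 1L, n_cab_per_group >= 1L,
            ca_reduction_filters >= 1L)
  structure(list(dims = as.integer(dims),
                 unet_base_filters = as.integer(unet_base_filters),
                 unet_depth = as.integer(unet_depth),
                 leaky_slope = leaky_slope,
                 rcan_filters = as.integer(rcan_filters),
                 n_residual_groups = as.integer(n_residual_groups),
                 n_cab_per_group = as.integer(n_cab_per_group),
                 ca_reduction_filters = as.integer(ca_reduction_filters),
                 conv_kernel = as.integer(conv_kernel),
                 output_kernel = as.integer(output_kernel)),
            class = "network_config")
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf("UNet-RCAN network config (%dD)\n", x$dims))
  cat(sprintf("  U-Net: depth %d, base filters %d (encoder %s)\n",
              x$unet_depth, x$unet_base_filters,
              paste(x$unet_base_filters * 2^(0:(x$unet_depth - 1)), collapse = " -> ")))
  cat(sprintf("  RCAN: %d RG x %d CAB, %d filters, CA reduction %d\n",
              x$n_residual_groups, x$n_cab_per_group, x$rcan_filters,
              x$ca_reduction_filters))
  invisible(x)
}

#' Build the first-stage residual U-Net
#'
#' Encoder stages are residual convolution blocks followed by stride-2
#' max-pooling, filters doubling after each pooling.  Decoder stages
#' upsample with a transposed convolution (kernel 2, stride 2), concatenate
#' the corresponding encoder feature routed through a channel attention
#' block (in place of a plain skip connection) and apply a residual
#' convolution block.  A final 1x1 convolution maps back to one channel.
#'
#' @param config A [network_config()].
#' @return An internal network module.
#' @export
build_unet <- function(config) {
  d <- config$dims
  s <- config$leaky_slope
  base <- config$unet_base_filters
  depth <- config$unet_depth
  ch <- as.integer(base * 2^(0:(depth - 1)))   # encoder stage channels
  enc <- list()
  pools <- list()
  cin <- 1L
  for (i in seq_len(depth)) {
    enc[[i]] <- nn_rcb(cin, ch[i], d, s)
    pools[[i]] <- nn_maxpool(d)
    cin <- ch[i]
  }
  bott <- nn_rcb(ch[depth], ch[depth] * 2L, d, s)
  ups <- list()
  skip_cab <- list()
  dec <- list()
  cu <- ch[depth] * 2L
  for (i in rev(seq_len(depth))) {
    ups[[i]] <- nn_convT(cu, ch[i], d)
    skip_cab[[i]] <- nn_cab(ch[i], config$ca_reduction_filters, d, s)
    dec[[i]] <- nn_rcb(2L * ch[i], ch[i], d, s)
    cu <- ch[i]
  }
  outc <- nn_conv(base, 1L, config$output_kernel, d)
  m <- nn_module("nn_unet",
                 subs = c(stats::setNames(enc, paste0("enc", seq_len(depth))),
                          stats::setNames(pools, paste0("pool", seq_len(depth))),
                          list(bott = bott),
                          stats::setNames(ups, paste0("up", seq_len(depth))),
                          stats::setNames(skip_cab, paste0("cab", seq_len(depth))),
                          stats::setNames(dec, paste0("dec", seq_len(depth))),
                          list(outc = outc)))
  m$depth <- depth
  m$dims <- d
  m$encoder_channels <- ch
  m
}

nn_forward.nn_unet <- function(mod, x) {
  depth <- mod$depth
  if (any(x$sp %% 2L^depth != 0L)) {
    stop("U-Net input spatial size must be divisible by 2^depth = ",
         2L^depth, "; pad the image (got ",
         paste(x$sp, collapse = "x"), ")", call. = FALSE)
  }
  e <- vector("list", depth)
  h <- x
  for (i in seq_len(depth)) {
    e[[i]] <- nn_forward(mod$subs[[paste0("enc", i)]], h)
    h <- nn_forward(mod$subs[[paste0("pool", i)]], e[[i]])
  }
  h <- nn_forward(mod$subs$bott, h)
  for (i in rev(seq_len(depth))) {
    u <- nn_forward(mod$subs[[paste0("up", i)]], h)
    sk <- nn_forward(mod$subs[[paste0("cab", i)]], e[[i]])
    h <- nn_act(cbind(u$v, sk$v), u$sp)
    h <- nn_forward(mod$subs[[paste0("dec", i)]], h)
  }
  mod$nch <- vapply(e, function(a) ncol(a$v), numeric(1))
  nn_forward(mod$subs$outc, h)
}

nn_backward.nn_unet <- function(mod, dy) {
  depth <- mod$depth
  dh <- nn_backward(mod$subs$outc, dy)
  dskip <- vector("list", depth)
  for (i in seq_len(depth)) {
    dh <- nn_backward(mod$subs[[paste0("dec", i)]], dh)
    cu <- ncol(dh$v) / 2L
    du <- nn_act(dh$v[, seq_len(cu), drop = FALSE], dh$sp)
    dsk <- nn_act(dh$v[, cu + seq_len(cu), drop = FALSE], dh$sp)
    dskip[[i]] <- nn_backward(mod$subs[[paste0("cab", i)]], dsk)
    dh <- nn_backward(mod$subs[[paste0("up", i)]], du)
  }
  dh <- nn_backward(mod$subs$bott, dh)
  for (i in rev(seq_len(depth))) {
    dh <- nn_backward(mod$subs[[paste0("pool", i)]], dh)
    dh <- nn_act(dh$v + dskip[[i]]$v, dh$sp)
    dh <- nn_backward(mod$subs[[paste0("enc", i)]], dh)
  }
  dh
}

#' Build the second-stage RCAN
#'
#' A head convolution lifts the 2-channel input (U-Net output concatenated
#' with the noisy image) to the trunk width; the trunk is
#' `n_residual_groups` residual groups of `n_cab_per_group` channel
#' attention blocks each (short skip per group), followed by a convolution
#' and one long skip connection; a 1x1 convolution maps to one channel.
#' There is no upscaling module: input and output shapes are equal.
#'
#' @param config A [network_config()].
#' @param in_channels Input channel count (2 in the two-step composite).
#' @return An internal network module.
#' @export
build_rcan <- function(config, in_channels = 2L) {
  d <- config$dims
  s <- config$leaky_slope
  f <- config$rcan_filters
  rgs <- lapply(seq_len(config$n_residual_groups), function(i)
    nn_rg(f, config$n_cab_per_group, config$ca_reduction_filters, d, s))
  m <- nn_module("nn_rcan", subs = list(
    head = nn_conv(in_channels, f, config$conv_kernel, d),
    trunk = do.call(nn_sequential, c(rgs, list(nn_conv(f, f, config$conv_kernel, d)))),
    tail = nn_conv(f, 1L, config$output_kernel, d)))
  m$in_channels <- as.integer(in_channels)
  m
}

nn_forward.nn_rcan <- function(mod, x) {
  h0 <- nn_forward(mod$subs$head, x)
  ht <- nn_forward(mod$subs$trunk, h0)
  nn_forward(mod$subs$tail, nn_act(h0$v + ht$v, h0$sp))  # long skip
}

nn_backward.nn_rcan <- function(mod, dy) {
  dsum <- nn_backward(mod$subs$tail, dy)
  dtrunk <- nn_backward(mod$subs$trunk, dsum)
  nn_backward(mod$subs$head, nn_act(dsum$v + dtrunk$v, dsum$sp))
}

#' Build the two-step UNet-RCAN restoration model
#'
#' Composes the residual U-Net and the RCAN: the RCAN input is the U-Net
#' output concatenated with the original noisy input (2 channels), so the
#' noisy image keeps guiding the second stage.  Weights are He-uniform
#' initialized under `seed`.
#'
#' @param config A [network_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `unet_rcan` with elements `config`, `net`
#'   (internal modules) and `history` (filled by [train_model()]).
#' @export
#' @examples
#' cfg <- network_config(unet_base_filters = 8, n_residual_groups = 1,
#'                       n_cab_per_group = 2)
#' model <- build_unet_rcan(cfg, seed = 1)
#' x <- matrix(runif(64 * 64), 64, 64)
#' dim(model_forward(model, x))
build_unet_rcan <- function(config, seed = 1L) {
  stopifnot(inherits(config, "network_config"))
  net <- with_seed(seed, {
    unet <- build_unet(config)
    rcan <- build_rcan(config, in_channels = 2L)
    # zero-init the output convolutions so the untrained composite starts
    # from a zero prediction and restoration is learned as a residual;
    # with random output heads the initial output magnitude grows with
    # depth and early optimizer steps are wasted recovering the scale
    unet$subs$outc$pars$W$v[] <- 0
    rcan$subs$tail$pars$W$v[] <- 0
    m <- nn_module("nn_unet_rcan", subs = list(unet = unet, rcan = rcan))
    m
  })
  structure(list(config = config, net = net, history = NULL, seed = seed),
            class = "unet_rcan")
}

nn_forward.nn_unet_rcan <- function(mod, x) {
  u <- nn_forward(mod$subs$unet, x)
  z <- nn_act(cbind(u$v, x$v), x$sp)   # RCAN input: [U-Net output || noisy]
  nn_forward(mod$subs$rcan, z)
}

nn_backward.nn_unet_rcan <- function(mod, dy) {
  dz <- nn_backward(mod$subs$rcan, dy)
  du <- nn_act(dz$v[, 1L, drop = FALSE], dz$sp)
  dx2 <- dz$v[, 2L, drop = FALSE]
  dx1 <- nn_backward(mod$subs$unet, du)
  nn_act(dx1$v + dx2, dy$sp)
}

#' Total number of trainable parameters
#'
#' @param model A `unet_rcan` model (or an internal module).
#' @return Integer parameter count.
#' @export
count_params <- function(model) {
  mod <- if (inherits(model, "unet_rcan")) model$net else model
  nn_count_params(mod)
}

# Forward pass of a model on a plain array (matrix or 3D array).
array_to_act <- function(x) {
  d <- dim(x)
  nn_act(matrix(as.numeric(x), ncol = 1L), as.integer(d))
}

act_to_array <- function(a) array(a$v[, 1L], dim = a$sp)

#' Run the network on an image without tiling
#'
#' @param model A `unet_rcan` model.
#' @param x A matrix (2D model) or 3D array (3D model).
#' @return Restored array of the same shape.
#' @export
model_forward <- function(model, x) {
  stopifnot(inherits(model, "unet_rcan"))
  if (is.null(dim(x))) x <- as.matrix(x)
  if (length(dim(x)) != model$config$dims)
    stop(sprintf("model is %dD but input has %d dimensions",
                 model$config$dims, length(dim(x))), call. = FALSE)
  act_to_array(nn_forward(model$net, array_to_act(x)))
}

# 1D blending ramp for overlap-tiled prediction.  The outer half of each
# overlap margin gets zero weight: those pixels sit closest to the tile
# border, where the tile's zero padding contaminates the prediction, and
# the neighboring tile covers them from its interior.
tile_ramp <- function(n, overlap, at_start, at_end) {
  w <- rep(1, n)
  if (overlap > 0) {
    m0 <- overlap %/% 2L
    ramp <- pmax(0, seq_len(overlap) - m0) / (overlap - m0)
    if (at_start) w[seq_len(overlap)] <- ramp
    if (at_end) w[n - overlap + seq_len(overlap)] <- rev(ramp)
  }
  w
}

#' Restore a full image by overlap-tiled inference
#'
#' Full STED frames (e.g. 2048 x 2048) are restored tile by tile with
#' linearly blended overlaps, so memory stays bounded.  With an overlap at
#' least as large as the network's receptive-field margin, the tiled result
#' matches the untiled forward pass.
#'
#' @param object A `unet_rcan` model.
#' @param image Input array (one frame/volume), shape preserved.
#' @param tile Tile edge length in pixels (`NULL` = whole image at once);
#'   must be divisible by `2^unet_depth`.
#' @param overlap Overlap between adjacent tiles in pixels.
#' @param ... Unused.
#' @return Restored array of the same shape as `image`.
#' @export
predict.unet_rcan <- function(object, image, tile = NULL, overlap = 32L, ...) {
  x <- image
  d <- dim(x)
  if (is.null(d)) {
    x <- as.matrix(x)
    d <- dim(x)
  }
  if (is.null(tile)) return(model_forward(object, x))
  tile <- as.integer(tile)
  div <- 2L^object$config$unet_depth
  if (tile %% div != 0L)
    stop("tile size must be divisible by 2^unet_depth = ", div, call. = FALSE)
  overlap <- min(as.integer(overlap), tile %/% 2L - 1L)
  step <- tile - overlap
  starts <- lapply(d, function(n) {
    if (n <= tile) return(1L)
    s <- seq(1L, n - tile, by = step)
    if (tail(s, 1L) + tile - 1L < n) s <- c(s, n - tile + 1L)
    s
  })
  acc <- array(0, d)
  wacc <- array(0, d)
  grid <- expand.grid(starts, KEEP.OUT.ATTRS = FALSE)
  for (r in seq_len(nrow(grid))) {
    s0 <- as.integer(grid[r, ])
    idx <- lapply(seq_along(d), function(ax) s0[ax]:min(s0[ax] + tile - 1L, d[ax]))
    sub <- do.call(`[`, c(list(x), idx, list(drop = FALSE)))
    pred <- model_forward(object, array(sub, vapply(idx, length, integer(1))))
    w1 <- lapply(seq_along(d), function(ax) {
      n <- length(idx[[ax]])
      tile_ramp(n, min(overlap, n %/% 2L),
                at_start = s0[ax] > 1L,
                at_end = (s0[ax] + n - 1L) < d[ax])
    })
    w <- Reduce(function(a, b) outer(a, b), w1)
    w <- array(w, dim(pred))
    old <- do.call(`[`, c(list(acc), idx, list(drop = FALSE)))
    oldw <- do.call(`[`, c(list(wacc), idx, list(drop = FALSE)))
    acc <- do.call(`[<-`, c(list(acc), idx, list(value = old + pred * w)))
    wacc <- do.call(`[<-`, c(list(wacc), idx, list(value = oldw + w)))
  }
  acc / wacc
}

#' @export
print.unet_rcan <- function(x, ...) {
  cat(sprintf("<unet_rcan> %dD two-step restoration model, %s parameters\n",
              x$config$dims, format(count_params(x), big.mark = ",")))
  if (!is.null(x$history))
    cat(sprintf("  trained %d epochs (best val loss %.4g)\n",
                nrow(x$history), min(x$history$val_loss)))
  invisible(x)
}

#' Save / load model checkpoints
#'
#' A checkpoint directory holds the weights (`weights.rds`) and the exact
#' architecture configuration (`config.yaml`).
#'
#' @param model A `unet_rcan` model.
#' @param path Checkpoint directory.
#' @return `save_checkpoint` the path, invisibly; `load_checkpoint` a model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "unet_rcan"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(model$config), file.path(path, "config.yaml"))
  saveRDS(list(state = nn_get_state(model$net), seed = model$seed,
               history = model$history),
          file.path(path, "weights.rds"))
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  cfg <- do.call(network_config, yaml::read_yaml(file.path(path, "config.yaml")))
  blob <- readRDS(file.path(path, "weights.rds"))
  model <- build_unet_rcan(cfg, seed = blob$seed %||% 1L)
  nn_set_state(model$net, blob$state)
  model$history <- blob$history
  model
}
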