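test_that("network configuration encodes the published architecture", {
  cfg <- network_config()
  expect_equal(cfg$unet_base_filters, 64L)
  expect_equal(cfg$unet_depth, 3L)
  expect_equal(cfg$n_residual_groups, 3L)
  expect_equal(cfg$n_cab_per_group, 8L)
  expect_equal(cfg$ca_reduction_filters, 4L)
  expect_equal(cfg$leaky_slope, 0.3)
  unet <- build_unet(cfg)
  expect_identical(unet$encoder_channels, c(64L, 128L, 256L))
  rcan <- build_rcan(cfg)
  expect_identical(rcan$in_channels, 2L)   # U-Net output || noisy input
  expect_error(network_config(dims = 4), "dims")
})

test_that("forward passes preserve shape in 2D and 3D and are deterministic", {
  m2 <- build_unet_rcan(tiny_config(2L), seed = 5)
  x2 <- matrix(runif(64 * 64), 64, 64)
  y2 <- model_forward(m2, x2)
  expect_identical(dim(y2), c(64L, 64L))
  expect_identical(model_forward(m2, x2), y2)
  expect_identical(model_forward(build_unet_rcan(tiny_config(2L), seed = 5), x2),
                   y2)                       # same seed, same weights
  z <- model_forward(m2, matrix(0, 64, 64))
  expect_true(all(is.finite(z)))

  m3 <- build_unet_rcan(tiny_config(3L), seed = 5)
  x3 <- array(runif(16 * 16 * 8), c(16, 16, 8))
  expect_identical(dim(model_forward(m3, x3)), c(16L, 16L, 8L))

  expect_error(model_forward(m2, matrix(0, 60, 60)), "divisible")
  expect_error(model_forward(m2, x3), "dimensions")
})

test_that("channel attention gates are sigmoid-bounded and multiplicative", {
  cab <- stedrestore:::nn_cab(4L, reduction = 2L, dims = 2L)
  x <- stedrestore:::nn_act(matrix(rnorm(64 * 4), 64, 4), c(8L, 8L))
  y <- stedrestore:::nn_forward(cab, x)
  g <- cab$cache$g
  expect_true(all(g > 0 & g < 1))
  # forcing the gate to zero reduces the CAB to its skip path
  cab$pars$bu$v[] <- -40
  cab$pars$Wu$v[] <- 0
  y0 <- stedrestore:::nn_forward(cab, x)
  expect_equal(y0$v, x$v, tolerance = 1e-12)
})

test_that("parameter count matches an independent layer-by-layer tally", {
  conv_n <- function(k, cin, cout, d) k^d * cin * cout + cout
  convT_n <- function(cin, cout, d) 2^d * cin * cout + cout
  rcb_n <- function(cin, cout, d) conv_n(3, cin, cout, d) +
    conv_n(3, cout, cout, d) + conv_n(1, cin, cout, d)
  cab_n <- function(c, r, d) 2 * conv_n(3, c, c, d) + (c * r + r) + (r * c + c)
  tally <- function(cfg) {
    d <- cfg$dims
    base <- cfg$unet_base_filters
    ch <- base * 2^(0:(cfg$unet_depth - 1))
    nc <- length(ch)
    unet <- rcb_n(1, ch[1], d)
    for (i in seq_len(nc - 1)) unet <- unet + rcb_n(ch[i], ch[i + 1], d)
    unet <- unet + rcb_n(ch[nc], 2 * ch[nc], d)       # bottleneck
    cu <- 2 * ch[nc]
    for (i in rev(seq_len(nc))) {
      unet <- unet + convT_n(cu, ch[i], d) +
        cab_n(ch[i], cfg$ca_reduction_filters, d) +
        rcb_n(2 * ch[i], ch[i], d)
      cu <- ch[i]
    }
    unet <- unet + conv_n(1, base, 1, d)
    f <- cfg$rcan_filters
    rcan <- conv_n(3, 2, f, d) +
      cfg$n_residual_groups *
        (cfg$n_cab_per_group * cab_n(f, cfg$ca_reduction_filters, d) +
         conv_n(3, f, f, d)) +
      conv_n(3, f, f, d) + conv_n(1, f, 1, d)
    unet + rcan
  }
  cfg2 <- network_config(dims = 2L)
  expect_identical(count_params(build_unet_rcan(cfg2, seed = 1)), tally(cfg2))
  cfg3 <- network_config(dims = 3L)
  expect_identical(count_params(build_unet_rcan(cfg3, seed = 1)), tally(cfg3))
  tiny <- tiny_config(2L)
  expect_identical(count_params(build_unet_rcan(tiny, seed = 1)), tally(tiny))
  # pure function of the configuration
  expect_identical(count_params(build_unet_rcan(tiny, seed = 1)),
                   count_params(build_unet_rcan(tiny, seed = 99)))
})

test_that("overlap-tiled prediction matches the untiled forward pass", {
  cfg <- network_config(dims = 2L, unet_base_filters = 4L, unet_depth = 1L,
                        n_residual_groups = 1L, n_cab_per_group = 1L)
  m <- build_unet_rcan(cfg, seed = 2)
  # give the zero-initialized output heads weights so the untrained
  # network emits a non-trivial image
  stedrestore:::with_seed(3, {
    m$net$subs$unet$subs$outc$pars$W$v[] <-
      rnorm(length(m$net$subs$unet$subs$outc$pars$W$v), sd = 0.1)
    m$net$subs$rcan$subs$tail$pars$W$v[] <-
      rnorm(length(m$net$subs$rcan$subs$tail$pars$W$v), sd = 0.1)
  })
  # saturate every channel-attention gate: the global average pooling in
  # a CAB sees the whole tile, so with unsaturated gates tiled inference
  # is inherently approximate; saturated gates isolate the tiling
  # machinery itself
  saturate <- function(mod) {
    if (inherits(mod, "nn_cab")) {
      mod$pars$Wu$v[] <- 0
      mod$pars$bu$v[] <- 40
    }
    for (s in mod$subs) saturate(s)
  }
  saturate(m$net)
  x <- matrix(runif(96 * 96), 96, 96)
  direct <- model_forward(m, x)
  expect_gt(max(abs(direct)), 0)
  tiled <- predict(m, x, tile = 64, overlap = 30)
  expect_lt(max(abs(tiled - direct)) / max(abs(direct)), 1e-4)
  expect_identical(predict(m, x), direct)    # tile = NULL, whole image
  # shift invariance: a constant input yields an interior constant up to
  # the natural 2^depth periodicity of the stride-2 up/down-sampling path
  yc <- model_forward(m, matrix(0.5, 96, 96))
  expect_lt(max(abs(yc[33:60, 33:60] - yc[35:62, 35:62])), 1e-8)
  expect_error(predict(m, x, tile = 31), "divisible")
})

test_that("checkpoints round-trip weights and configuration", {
  m <- build_unet_rcan(tiny_config(2L), seed = 3)
  x <- matrix(runif(32 * 32), 32, 32)
  dir <- tempfile("ckpt")
  save_checkpoint(m, dir)
  back <- load_checkpoint(dir)
  expect_identical(model_forward(back, x), model_forward(m, x))
  expect_identical(back$config, m$config)
})
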