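test_that("Charbonnier loss satisfies its identities and limits", {
  y <- matrix(runif(64), 8, 8)
  yh <- matrix(runif(64), 8, 8)
  expect_identical(charbonnier_loss(y, y), 1e-3)
  expect_identical(charbonnier_loss(y, y, reduction = "global"), 1e-3)
  expect_identical(charbonnier_loss(y, yh), charbonnier_loss(yh, y))
  # single-pixel worked example
  expect_equal(charbonnier_loss(matrix(1), matrix(0)), sqrt(1 + 1e-6))
  # L1 limit: at |diff| = 1000 * epsilon the ratio to the L1 mean is ~1
  big <- y + 1
  expect_equal(charbonnier_loss(y, big) / mean(abs(y - big)), 1,
               tolerance = 1e-6)
  # permutation equivariance
  perm <- sample(64)
  expect_equal(charbonnier_loss(matrix(y[perm], 8), matrix(yh[perm], 8)),
               charbonnier_loss(y, yh))
  expect_error(charbonnier_loss(y, matrix(0, 4, 4)), "shapes")
})

test_that("edge loss is Charbonnier on Laplacians and kills constants", {
  y <- matrix(runif(64), 8, 8)
  expect_identical(edge_loss(y, y), 1e-3)
  # global constant offsets are invisible to the Laplacian
  expect_equal(edge_loss(y, y + 0.37), 1e-3)
  # the filter matches a brute-force direct-summation 4-neighbor stencil
  lap <- stedrestore:::laplacian_filter(y)
  brute <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8) {
    up <- y[max(i - 1, 1), j]; dn <- y[min(i + 1, 8), j]
    lf <- y[i, max(j - 1, 1)]; rt <- y[i, min(j + 1, 8)]
    brute[i, j] <- up + dn + lf + rt - 4 * y[i, j]
  }
  expect_equal(lap, brute, tolerance = 1e-12)
})

test_that("total loss recovers the edge weight alpha on any input pair", {
  lc <- loss_config()
  expect_equal(lc$epsilon, 1e-3)
  expect_equal(lc$alpha, 0.05)
  y <- matrix(runif(256), 16, 16)
  yh <- matrix(runif(256), 16, 16)
  expect_equal(total_loss(y, y, lc), 1e-3 * 1.05)   # epsilon * (1 + alpha)
  alpha_hat <- (total_loss(y, yh, lc) - charbonnier_loss(y, yh)) /
    edge_loss(y, yh)
  expect_equal(alpha_hat, 0.05, tolerance = 1e-12)
  lc0 <- loss_config(alpha = 0)
  expect_equal(total_loss(y, yh, lc0), charbonnier_loss(y, yh))
  # analytic gradient matches central differences
  g <- stedrestore:::total_loss_grad(y, yh, lc)
  idx <- c(1, 17, 100, 256)
  for (i in idx) {
    h <- 1e-6
    ya <- yh; ya[i] <- ya[i] + h
    yb <- yh; yb[i] <- yb[i] - h
    num <- (total_loss(y, ya, lc) - total_loss(y, yb, lc)) / (2 * h)
    expect_equal(g[i], num, tolerance = 1e-4)
  }
})

test_that("cosine annealing interpolates between its endpoints", {
  expect_identical(cosine_lr(0, 200), 1e-4)
  expect_equal(cosine_lr(199, 200), 1e-6)
  expect_equal(cosine_lr(100, 201), (1e-4 + 1e-6) / 2)
  lrs <- vapply(0:199, cosine_lr, numeric(1), total_epochs = 200)
  expect_true(all(diff(lrs) <= 0))
  expect_error(cosine_lr(200, 200), "epoch")
})

test_that("short training runs descend and are seed-reproducible", {
  pair <- small_pair(seed = 21, shape = c(96L, 96L))
  raw <- extract_patches(pair, c(32, 32), max_patches = 8, seed = 2)
  ps <- filter_patches(raw, 0.2)
  ps$val_idx <- length(ps)
  cfg <- network_config(dims = 2L, unet_base_filters = 4L, unet_depth = 2L,
                        rcan_filters = 8L, n_residual_groups = 1L,
                        n_cab_per_group = 1L)
  tc <- train_config(epochs = 3L, initial_lr = 1e-3, seed = 4L)
  m1 <- train_model(build_unet_rcan(cfg, seed = 6), ps, tc)
  expect_s3_class(m1$history, "data.frame")
  expect_equal(nrow(m1$history), 3L)
  expect_lt(m1$history$train_loss[3], m1$history$train_loss[1])
  m2 <- train_model(build_unet_rcan(cfg, seed = 6), ps, tc)
  expect_identical(m1$history, m2$history)
})
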