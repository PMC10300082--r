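test_that("patch extraction tiles and aligns both members", {
  pair <- list(noisy = matrix(runif(128 * 128), 128, 128),
               gt = matrix(runif(128 * 128), 128, 128))
  tiled <- extract_patches(pair, c(64, 64), stride = 64)
  expect_equal(length(tiled$noisy), 4L)       # 128/64 tiling
  # noisy and gt offsets are identical by construction
  for (i in seq_along(tiled$noisy)) {
    off <- unlist(tiled$provenance[i, c("offset1", "offset2")])
    expect_identical(tiled$noisy[[i]],
                     pair$noisy[off[1]:(off[1] + 63), off[2]:(off[2] + 63)])
    expect_identical(tiled$gt[[i]],
                     pair$gt[off[1]:(off[1] + 63), off[2]:(off[2] + 63)])
  }
  rnd <- extract_patches(pair, c(64, 64), max_patches = 10, seed = 4)
  expect_equal(length(rnd$noisy), 10L)
  expect_identical(extract_patches(pair, c(64, 64), max_patches = 10,
                                   seed = 4)$provenance, rnd$provenance)
  expect_error(extract_patches(pair, c(256, 256)), "fit inside")
})

test_that("patch normalization divides by the maximum and flags empties", {
  p <- matrix(7, 16, 16)
  expect_true(all(normalize_patch(p) == 1))
  z <- matrix(0, 16, 16)
  expect_true(isTRUE(attr(normalize_patch(z), "flagged_empty")))
  expect_true(all(normalize_patch(z) == 0))
  q <- matrix(runif(256), 16, 16)
  expect_identical(which.max(normalize_patch(q)), which.max(q))
})

test_that("content filtering matches a brute-force norm ranking and is monotone", {
  # 16 patches, patch k holding k unit pixels: L2 norm sqrt(k)
  mk <- function(k) {
    m <- matrix(0, 16, 16)
    m[seq_len(k)] <- 1
    m
  }
  patches <- structure(list(noisy = lapply(1:16, mk), gt = lapply(1:16, mk),
                            provenance = data.frame(patch = 1:16,
                                                    offset1 = 1, offset2 = 1),
                            patch_shape = c(16L, 16L)),
                       class = "patch_pairs")
  ps <- filter_patches(patches, 0.3)
  expected_keep <- which(sqrt(1:16) / sqrt(16) >= 0.3)  # brute force
  expect_identical(ps$provenance$patch, expected_keep)
  expect_equal(ps$norms, sqrt(expected_keep) / 4)

  # threshold 0 keeps everything; a bright patch survives next to a dim one
  expect_equal(length(filter_patches(patches, 0)), 16L)

  # monotone over the working range 0.2-0.4: raising the threshold never
  # admits a previously discarded patch
  kept <- lapply(seq(0.2, 0.4, by = 0.05), function(th)
    filter_patches(patches, th)$provenance$patch)
  for (i in seq_len(length(kept) - 1)) {
    expect_true(all(kept[[i + 1]] %in% kept[[i]]))
  }
  expect_error(filter_patches(structure(list(noisy = list(), gt = list()),
                                        class = "patch_pairs"), 0.3), "empty")
})

test_that("content norms are taken before max normalization, so background-only patches drop", {
  # A structured patch (bright filament-like counts) versus a patch of
  # pure sparse Poisson background.  After per-patch max normalization
  # the background patch's norm would exceed the structured one (its few
  # single-count pixels all rescale to 1), inverting the ranking; on raw
  # counts the structured patch dominates and the background patch is
  # discarded.
  struct <- matrix(0, 64, 64)
  struct[32, ] <- 50                       # one thin bright filament
  bg <- matrix(stedrestore:::with_seed(9, rpois(64 * 64, 0.1)), 64, 64)
  norm_after_maxnorm <- function(p) sqrt(sum((p / max(p))^2))
  expect_gt(norm_after_maxnorm(bg), norm_after_maxnorm(struct))

  patches <- structure(list(noisy = list(struct, bg), gt = list(struct, bg),
                            provenance = data.frame(patch = 1:2,
                                                    offset1 = 1, offset2 = 1),
                            patch_shape = c(64L, 64L)),
                       class = "patch_pairs")
  ps <- filter_patches(patches, 0.3)
  expect_identical(ps$provenance$patch, 1L)
  expect_equal(max(ps$gt[[1]]), 1)   # survivors are max-normalized
})

test_that("patch sets serialize losslessly and split reproducibly", {
  pair <- small_pair(seed = 3)
  ps <- filter_patches(extract_patches(pair, c(32, 32), max_patches = 12,
                                       seed = 5), 0.2)
  path <- tempfile()
  write_patchset(ps, path)
  back <- read_patchset(path)
  expect_identical(back$gt, ps$gt)
  expect_identical(back$noisy, ps$noisy)
  expect_true(file.exists(paste0(path, ".json")))

  s1 <- split_patchset(ps, 0.25, seed = 7)
  s2 <- split_patchset(ps, 0.25, seed = 7)
  expect_identical(s1$val_idx, s2$val_idx)
  expect_equal(length(s1$val_idx), round(0.25 * length(ps)))
})
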