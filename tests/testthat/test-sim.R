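test_that("phantom rendering is deterministic, non-negative and respects primitives", {
  ph <- phantom("filaments", shape = c(96, 96), seed = 11)
  a <- render_phantom(ph)
  b <- render_phantom(ph)
  expect_identical(strip(a), strip(b))
  expect_true(all(a >= 0))
  expect_identical(dim(a), c(96L, 96L))

  # zero structures: all-zero grid
  empty <- phantom("puncta", shape = c(32, 32), structures = list())
  expect_true(all(render_phantom(empty) == 0))

  # a point source at an integer pixel deposits exactly one nonzero pixel
  pt <- phantom("puncta", shape = c(32, 32),
                structures = list(list(type = "point", pos = c(17, 9),
                                       amplitude = 2.5)))
  img <- render_phantom(pt)
  expect_equal(sum(img != 0), 1)
  expect_equal(img[17, 9], 2.5)

  # primitives outside the grid are rejected
  bad <- phantom("puncta", shape = c(32, 32),
                 structures = list(list(type = "point", pos = c(40, 9),
                                        amplitude = 1)))
  expect_error(render_phantom(bad), "outside")
})

test_that("effective FWHM follows the STED scaling law", {
  expect_equal(effective_fwhm(optics_model(240, 0, 0.05)), 240)
  expect_equal(effective_fwhm(optics_model(240, 0.05, 0.05)), 240 / sqrt(2))
  expect_equal(effective_fwhm(optics_model(240, 0.75, 0.05)), 60)  # 240/sqrt(16)
  expect_error(optics_model(240, -0.1, 0.05), "non-negative")
  expect_error(optics_model(240, 0.5, 0), "positive")
  # strictly decreasing in depletion power
  fw <- vapply(seq(0, 1, by = 0.1),
               function(p) effective_fwhm(optics_model(240, p, 0.05)),
               numeric(1))
  expect_true(all(diff(fw) < 0))
})

test_that("PSF blur conserves intensity and reproduces the target FWHM", {
  opt <- std_optics()
  z <- array(0, c(65, 65)); z[33, 33] <- 1
  zb <- psf_blur(z, opt, 20)
  expect_equal(sum(zb), 1, tolerance = 1e-6)     # impulse mass conserved
  fit <- fwhm_line_profile(zb, c(33, 13), c(33, 53), 20)
  expect_true(fit$converged)
  expect_equal(fit$fwhm_nm, effective_fwhm(opt), tolerance = 0.02)
  # uniform input stays uniform in the interior
  u <- array(1, c(48, 48))
  ub <- psf_blur(u, opt, 20)
  expect_equal(max(abs(ub[16:32, 16:32] - 1)), 0, tolerance = 1e-9)
  # sub-pixel FWHM clamps with a warning
  expect_warning(psf_blur(z, optics_model(240, 1, 0.001), 300), "clamped")
})

test_that("acquisition draws Poisson counts with dwell-linear expectation", {
  opt <- std_optics()
  img <- array(1, c(100, 100))
  expect_true(all(acquire(img, acquisition_model(0, 40)) == 0))

  # moments at expectation 5: 10,000 draws
  lam5 <- array(5 / 40, c(100, 100))
  counts <- acquire(lam5, acquisition_model(1, 40, background = 0), seed = 21)
  expect_lt(abs(mean(counts) - 5), 0.07)
  expect_lt(abs(var(as.vector(counts)) / mean(counts) - 1), 0.05)
  # chi-square dispersion test at alpha = 0.01
  disp <- sum((counts - mean(counts))^2) / mean(counts)
  expect_gt(disp, qchisq(0.005, 1e4 - 1))
  expect_lt(disp, qchisq(0.995, 1e4 - 1))

  # doubling dwell time doubles the mean count
  c1 <- acquire(lam5, acquisition_model(1, 40, background = 0), seed = 3)
  c2 <- acquire(lam5, acquisition_model(2, 40, background = 0), seed = 4)
  expect_equal(mean(c2) / mean(c1), 2, tolerance = 0.05)

  # determinism under a fixed seed
  expect_identical(acquire(lam5, acquisition_model(1, 40), seed = 5),
                   acquire(lam5, acquisition_model(1, 40), seed = 5))
})

test_that("simulated pairs reproduce the fast/slow exposure contrast", {
  pair <- small_pair(seed = 5)
  ratio <- mean(pair$gt) / mean(pair$noisy)
  expect_equal(ratio, 2.3 / 0.072, tolerance = 0.05)  # >30-fold contrast
  expect_identical(strip(small_pair(seed = 5)$noisy), strip(pair$noisy))
  tr <- strip(pair$truth)
  # fast member is noisier than the slow member against the common truth
  p_fast <- psnr(tr, strip(pair$noisy) / (40 * 0.072))
  p_slow <- psnr(tr, strip(pair$gt) / (40 * 2.3))
  expect_lt(p_fast, p_slow)
  expect_error(simulate_pair(phantom(seed = 1), std_optics(),
                             dwell_fast = 3, dwell_slow = 2), "smaller")
})

test_that("time-lapse bleaching decays exponentially in cumulative dose", {
  ph <- phantom("filaments", shape = c(64, 64), seed = 2)
  opt <- std_optics()
  acq <- acquisition_model(2.3, 40, background = 0)
  # no bleaching: stationary mean intensity
  tl0 <- simulate_timelapse(ph, opt, acq, n_frames = 12, bleach_rate = 0,
                            seed = 3)
  m <- apply(tl0, 3, mean)
  expect_lt(max(abs(m - mean(m))) / mean(m), 0.05)

  # half-signal frame matches the closed form 1 + ln2/(rate * dwell)
  rate <- log(2) / (8 * 2.3)
  tl <- simulate_timelapse(ph, opt, acq, n_frames = 16, bleach_rate = rate,
                           seed = 4)
  bc <- bleach_curve(tl)
  expect_equal(bc$half_frame, 9, tolerance = 0.1)

  # at equal rate, a fast-dwell series decays less per frame
  acqf <- acquisition_model(0.054, 40, background = 0)
  tlf <- simulate_timelapse(ph, opt, acqf, n_frames = 16, bleach_rate = rate,
                            seed = 4)
  decay_slow <- mean(tl[, , 16]) / mean(tl[, , 1])
  decay_fast <- mean(tlf[, , 16]) / mean(tlf[, , 1])
  expect_gt(decay_fast, decay_slow)
})
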