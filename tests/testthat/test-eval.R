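test_that("PSNR and NMSE satisfy their closed forms and orderings", {
  ref <- matrix(runif(64 * 64), 64, 64)
  ref <- ref / max(ref)                       # data range exactly 1
  expect_equal(psnr(ref, ref), 100)           # capped sentinel
  expect_equal(psnr(ref, ref - 0.1, data_range = 1), 20)  # 10*log10(1/0.01)
  expect_error(psnr(ref, ref[1:10, 1:10]), "shapes")

  expect_equal(nmse(ref, ref), 0)
  expect_equal(nmse(ref, ref * 0), 1)
  expect_equal(nmse(ref, 2 * ref), 1)
  expect_error(nmse(ref * 0, ref), "all-zero")

  # PSNR decreases monotonically as the dwell time shortens
  ph <- phantom("filaments", shape = c(64, 64), seed = 3)
  truth <- psf_blur(render_phantom(ph), std_optics(), 20)
  ps <- vapply(c(2.3, 0.5, 0.1), function(dw) {
    img <- acquire(truth, acquisition_model(dw, 40, background = 0), seed = 9)
    psnr(strip(truth), strip(img) / (40 * dw))
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("MS-SSIM is reflexive-optimal, symmetric and noise-ordered", {
  base <- matrix(0, 200, 200)
  base[, seq(10, 190, by = 20)] <- 1
  base <- stedrestore:::separable_convolve(base, rep(list(
    stedrestore:::gaussian_kernel_1d(2)), 2))
  expect_equal(ms_ssim(base, base), 1)
  noisy <- poissonize(base * 50, 1, seed = 4) / 50
  s1 <- ms_ssim(base, noisy)
  expect_equal(s1, ms_ssim(noisy, base))
  indep <- matrix(stedrestore:::with_seed(5, runif(200 * 200)), 200, 200)
  expect_gt(s1, ms_ssim(base, indep))
  expect_lt(ms_ssim(base, noisy), 1)
  # noisier copies score lower
  noisier <- poissonize(base * 5, 1, seed = 6) / 5
  expect_lt(ms_ssim(base, noisier), s1)
  expect_error(ms_ssim(matrix(0, 32, 32), matrix(0, 32, 32)), "minimum size")
})

test_that("FWHM line profiles are unbiased across widths", {
  mk_ridge <- function(sig, n = 64) {
    x <- matrix(rep(1:n, each = n), n, n)
    exp(-(x - n / 2)^2 / (2 * sig^2))
  }
  for (sig in c(1.5, 2.5, 4)) {
    img <- mk_ridge(sig)
    fit <- fwhm_line_profile(img, c(32, 8), c(32, 56), pixel_size = 20)
    expect_true(fit$converged)
    expect_equal(fit$fwhm_nm, 2 * sqrt(2 * log(2)) * sig * 20,
                 tolerance = 0.005)
  }
  # translation invariance along the ridge
  img <- mk_ridge(2)
  f1 <- fwhm_line_profile(img, c(16, 8), c(16, 56), pixel_size = 20)
  f2 <- fwhm_line_profile(img, c(48, 8), c(48, 56), pixel_size = 20)
  expect_equal(f1$fwhm_nm, f2$fwhm_nm, tolerance = 1e-8)
  # aggregate over profiles reports mean and SEM
  agg <- fwhm_profiles(img, lapply(seq(12, 52, length.out = 10), function(y)
    list(p0 = c(y, 8), p1 = c(y, 56))), pixel_size = 20)
  expect_equal(agg$n, 10L)
  expect_equal(agg$mean_nm, 2.3548 * 2 * 20, tolerance = 0.01)
  expect_true(is.finite(agg$sem_nm))
})

test_that("decorrelation resolution uses the published defaults and needs variance", {
  f <- formals(decorrelation_resolution)
  expect_equal(f$radius_min, 0)
  expect_equal(f$radius_max, 1)
  expect_equal(f$nr, 50L)
  expect_equal(f$ng, 10L)
  expect_error(decorrelation_resolution(matrix(1, 32, 32), 20), "variance")
})

test_that("decorrelation and FWHM profiling agree on high-SNR bead images", {
  img <- bead_image(power = 0.75)
  dres <- decorrelation_resolution(img, 20)
  # locate an isolated bright bead and profile across it
  sm <- stedrestore:::separable_convolve(img, rep(list(
    stedrestore:::gaussian_kernel_1d(1)), 2))
  ctr <- arrayInd(which.max(sm[65:448, 65:448]), c(384L, 384L)) + 64L
  fit <- fwhm_line_profile(img, c(ctr[1], ctr[2] - 10),
                           c(ctr[1], ctr[2] + 10), pixel_size = 20)
  expect_true(fit$converged)
  expect_lt(abs(dres$resolution_nm - fit$fwhm_nm) / fit$fwhm_nm, 0.2)
})

test_that("bleach curves track the simulated decay", {
  ph <- phantom("filaments", shape = c(64, 64), seed = 2)
  acq <- acquisition_model(2.3, 40, background = 0)
  tl0 <- simulate_timelapse(ph, std_optics(), acq, n_frames = 10,
                            bleach_rate = 0, seed = 5)
  bc0 <- bleach_curve(tl0)
  expect_true(all(bc0$trace / max(bc0$trace) > 0.9))   # stationary
  expect_true(is.na(bc0$half_frame))
  expect_equal(max(bc0$l2_norm), 1)

  rate <- log(2) / (8 * 2.3)
  tl <- simulate_timelapse(ph, std_optics(), acq, n_frames = 16,
                           bleach_rate = rate, seed = 6)
  bc <- bleach_curve(tl)
  expect_equal(bc$half_frame, 9, tolerance = 0.1)      # 1 + ln2/(rate*dwell)
  # restored frames carry no bleaching trend of their own (patches are
  # max-normalized); the noisy-derived L2 vector reinstates the decay
  pred <- array(1, dim(tl))
  bcp <- bleach_curve(tl, pred)
  expect_equal(bcp$half_frame, bc$half_frame, tolerance = 0.15)
  expect_error(bleach_curve(tl[, , 1, drop = FALSE]), "2 frames")
})

test_that("metrics reports aggregate over images and error maps subtract", {
  ref <- matrix(runif(200 * 200), 200, 200)
  tests <- list(ref, pmin(ref + 0.05, 1))
  rep_ <- metrics_report(list(ref, ref), tests)
  expect_equal(nrow(rep_$per_image), 2L)
  expect_equal(rep_$per_image$nmse[1], 0)
  expect_true(all(c("mean", "sd") %in% names(rep_$aggregate$psnr)))
  em <- error_map(tests[[2]], ref)
  expect_true(all(em >= 0))
  expect_equal(error_map(tests[[2]], ref, signed = TRUE)[1, 1],
               tests[[2]][1, 1] - ref[1, 1])
})
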