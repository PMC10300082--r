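# Quantitative assessment of restorations: PSNR, NMSE, MS-SSIM, resolution
# estimation (Gaussian line-profile FWHM and decorrelation analysis) and
# photobleaching curves.

#' Peak signal-to-noise ratio
#'
#' `10 * log10(data_range^2 / MSE)` in dB.  Identical images (MSE 0) are
#' reported with a capped sentinel of 100 dB.
#'
#' @param reference Reference image.
#' @param test Test image, same shape.
#' @param data_range Dynamic range (default: maximum of the reference).
#' @return PSNR in dB.
#' @export
psnr <- function(reference, test, data_range = max(reference)) {
  check_same_shape(reference, test)
  if (data_range <= 0) stop("data_range must be positive", call. = FALSE)
  mse <- mean((reference - test)^2)
  if (mse == 0) return(100)
  min(100, 10 * log10(data_range^2 / mse))
}

#' Normalized mean squared error
#'
#' `sum((reference - test)^2) / sum(reference^2)`; 0 iff the images are
#' identical, 1 for an all-zero prediction.
#'
#' @param reference Reference image (not all-zero).
#' @param test Test image, same shape.
#' @return Dimensionless NMSE.
#' @export
nmse <- function(reference, test) {
  check_same_shape(reference, test)
  denom <- sum(reference^2)
  if (denom == 0) stop("reference image is all-zero", call. = FALSE)
  sum((reference - test)^2) / denom
}

# Valid-region Gaussian filtering used by SSIM (11x11 window, sigma 1.5).
ssim_filter <- function(img, kern) {
  r <- (length(kern) - 1L) / 2L
  out <- separable_convolve(img, rep(list(kern), 2L))
  d <- dim(img)
  out[(r + 1):(d[1] - r), (r + 1):(d[2] - r), drop = FALSE]
}

ssim_cs <- function(a, b, data_range, kern) {
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  mu_a <- ssim_filter(a, kern)
  mu_b <- ssim_filter(b, kern)
  saa <- ssim_filter(a * a, kern) - mu_a^2
  sbb <- ssim_filter(b * b, kern) - mu_b^2
  sab <- ssim_filter(a * b, kern) - mu_a * mu_b
  cs <- (2 * sab + C2) / (saa + sbb + C2)
  l <- (2 * mu_a * mu_b + C1) / (mu_a^2 + mu_b^2 + C1)
  list(cs = mean(cs), l = mean(l * cs))
}

downsample2 <- function(img) {
  d <- dim(img) %/% 2L * 2L
  img <- img[seq_len(d[1]), seq_len(d[2]), drop = FALSE]
  (img[seq(1, d[1], 2), seq(1, d[2], 2)] +
   img[seq(2, d[1], 2), seq(1, d[2], 2)] +
   img[seq(1, d[1], 2), seq(2, d[2], 2)] +
   img[seq(2, d[1], 2), seq(2, d[2], 2)]) / 4
}

#' Multi-scale structural similarity index
#'
#' Standard MS-SSIM with the canonical five scale weights
#' (0.0448, 0.2856, 0.3001, 0.2363, 0.1333), an 11x11 Gaussian window of
#' sigma 1.5, and 2x2 average-pool downsampling between scales.
#' Symmetric; 1 for identical images.
#'
#' @param reference,test 2D images of identical shape.
#' @param scales Number of dyadic scales (default 5).
#' @param data_range Dynamic range (default: max of both images).
#' @return MS-SSIM in `[0, 1]` (clipped at 0).
#' @export
ms_ssim <- function(reference, test, scales = 5L,
                    data_range = max(reference, test)) {
  check_same_shape(reference, test)
  stopifnot(scales >= 1L, scales <= 5L)
  weights <- c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)[seq_len(scales)]
  min_size <- 11L * 2L^(scales - 1L)
  if (min(dim(reference)) < min_size) {
    stop(sprintf("image too small for %d scales; minimum size is %d pixels",
                 scales, min_size), call. = FALSE)
  }
  kern <- gaussian_kernel_1d(1.5, truncate = 10 / 3)  # 11-tap window
  stopifnot(length(kern) == 11L)
  a <- reference
  b <- test
  vals <- numeric(scales)
  for (s in seq_len(scales)) {
    st <- ssim_cs(a, b, data_range, kern)
    vals[s] <- if (s == scales) st$l else st$cs
    if (s < scales) {
      a <- downsample2(a)
      b <- downsample2(b)
    }
  }
  vals <- pmax(vals, 0)
  prod(vals^weights)
}

#' Resolution from a Gaussian fit to a line profile
#'
#' Samples the image along a line segment by bilinear interpolation, fits
#' a Gaussian with offset by least squares, and reports
#' `FWHM = 2 * sqrt(2 * log(2)) * sigma` in nm with the fit standard
#' error.  Non-converging fits are flagged so callers can exclude them
#' from aggregates.
#'
#' @param image 2D image.
#' @param p0,p1 Line endpoints `c(y, x)` in pixel coordinates (1-based).
#' @param pixel_size Pixel size in nm.
#' @param n_samples Samples along the profile (default: one per pixel, so
#'   axis-aligned profiles with integer endpoints sample the lattice
#'   exactly and incur no interpolation bias).
#' @return List with `fwhm_nm`, `se_nm`, `sigma_px`, `converged`, `fit`.
#' @export
fwhm_line_profile <- function(image, p0, p1,
                              pixel_size = attr(image, "pixel_size"),
                              n_samples = NULL) {
  if (is.null(pixel_size)) stop("pixel_size is required", call. = FALSE)
  len_px <- sqrt(sum((p1 - p0)^2))
  n <- n_samples %||% max(9L, ceiling(len_px) + 1L)
  t <- seq(0, 1, length.out = n)
  pts <- cbind(p0[1] + t * (p1[1] - p0[1]), p0[2] + t * (p1[2] - p0[2]))
  prof <- bilinear_sample(image, pts)
  s <- t * len_px  # position along the profile in pixels
  df <- data.frame(s = s, v = prof)
  mu0 <- s[which.max(prof)]
  a0 <- max(prof) - min(prof)
  sig0 <- max(len_px / 8, 0.5)
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ a * exp(-(s - mu)^2 / (2 * sig^2)) + c0,
                      data = df,
                      start = list(a = a0, mu = mu0, sig = sig0,
                                   c0 = min(prof)),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(fwhm_nm = NA_real_, se_nm = NA_real_, sigma_px = NA_real_,
                converged = FALSE, fit = NULL))
  }
  co <- summary(fit)$coefficients
  sig <- abs(co["sig", "Estimate"])
  se <- co["sig", "Std. Error"]
  k <- 2 * sqrt(2 * log(2))
  list(fwhm_nm = k * sig * pixel_size, se_nm = k * se * pixel_size,
       sigma_px = sig, converged = TRUE, fit = fit)
}

#' Aggregate FWHM over several line profiles
#'
#' @param image 2D image.
#' @param lines List of `list(p0 =, p1 =)` endpoint pairs.
#' @param pixel_size Pixel size in nm.
#' @return List with `mean_nm`, `sem_nm`, `n`, and the per-profile values.
#' @export
fwhm_profiles <- function(image, lines,
                          pixel_size = attr(image, "pixel_size")) {
  vals <- vapply(lines, function(ln) {
    r <- fwhm_line_profile(image, ln$p0, ln$p1, pixel_size)
    if (isTRUE(r$converged)) r$fwhm_nm else NA_real_
  }, numeric(1))
  ok <- vals[is.finite(vals)]
  list(mean_nm = mean(ok), sem_nm = stats::sd(ok) / sqrt(length(ok)),
       n = length(ok), fwhm_nm = vals)
}

#' Image resolution by decorrelation analysis
#'
#' Parameter-free resolution estimation from the decorrelation of the
#' image spectrum: the normalized spectrum is radially masked at `nr`
#' radii between `radius_min` and `radius_max` (fractions of the Nyquist
#' frequency) and cross-correlated with the original spectrum; the
#' procedure is repeated for `ng` Gaussian high-pass filtered versions of
#' the image, and the highest peak frequency over all decorrelation
#' curves defines the cutoff `kc`.  Resolution is `2 * pixel_size / kc`.
#' Defaults are radius range 0-1, `nr = 50`, `ng = 10`.
#'
#' @param image 2D image with nonzero variance.
#' @param pixel_size Pixel size in nm.
#' @param radius_min,radius_max Mask radius range (fraction of Nyquist).
#' @param nr Number of mask radii.
#' @param ng Number of high-pass filter widths.
#' @param apodize Fade image edges with a raised-cosine border (on by
#'   default; suppresses spectral leakage from non-periodic borders).
#' @return List with `resolution_nm`, `kc` (cutoff as Nyquist fraction)
#'   and the decorrelation curves.
#' @export
decorrelation_resolution <- function(image, pixel_size = attr(image, "pixel_size"),
                                     radius_min = 0, radius_max = 1,
                                     nr = 50L, ng = 10L, apodize = TRUE) {
  if (is.null(pixel_size)) stop("pixel_size is required", call. = FALSE)
  if (stats::sd(image) == 0) stop("image variance is zero", call. = FALSE)
  d <- dim(image)
  x <- image - mean(image)
  if (apodize) {
    w <- lapply(d, function(n) {
      e <- max(4L, round(0.1 * n))
      ramp <- 0.5 * (1 - cos(pi * seq_len(e) / (e + 1)))
      c(ramp, rep(1, n - 2 * e), rev(ramp))
    })
    x <- x * outer(w[[1]], w[[2]])
  }
  F <- stats::fft(x)
  # normalized frequency per axis: 0..1 at Nyquist
  fr <- lapply(d, function(n) {
    k <- 0:(n - 1)
    k <- ifelse(k > n %/% 2, k - n, k)
    k / (n / 2)
  })
  rho <- sqrt(outer(fr[[1]]^2, fr[[2]]^2, `+`))
  keep <- rho <= 1
  A <- Mod(F)[keep]
  rv <- rho[keep]
  ord <- order(rv)
  rv <- rv[ord]
  A <- A[ord]
  radii <- seq(radius_min, radius_max, length.out = nr)
  # high-pass widths in normalized frequency, equivalent to real-space
  # Gaussian blurs of ~4 px down to ~0.15 px
  sig_hp <- exp(seq(log(0.08), log(2.1), length.out = ng))
  curves <- matrix(0, nr, ng + 1L)
  peak_r <- rep(NA_real_, ng + 1L)
  for (g in 0:ng) {
    Ag <- if (g == 0) A else A * (1 - exp(-rv^2 / (2 * sig_hp[g]^2)))
    tot <- sum(Ag^2)
    if (tot == 0) next
    cumA <- cumsum(Ag)
    idx <- findInterval(radii, rv)
    dcurve <- ifelse(idx > 0, cumA[pmax(idx, 1)] / sqrt(tot * pmax(idx, 1)), 0)
    curves[, g + 1L] <- dcurve
    # local maxima strictly inside the radius range
    if (nr >= 3) {
      dm <- which(dcurve[2:(nr - 1)] > dcurve[1:(nr - 2)] &
                  dcurve[2:(nr - 1)] >= dcurve[3:nr]) + 1L
      dm <- dm[dcurve[dm] > 1e-3]
      if (length(dm) > 0) peak_r[g + 1L] <- radii[max(dm)]
    }
  }
  if (all(is.na(peak_r))) {
    stop("no decorrelation peak found; use a larger or noisier image",
         call. = FALSE)
  }
  kc <- max(peak_r, na.rm = TRUE)
  list(resolution_nm = 2 * pixel_size / kc, kc = kc,
       radii = radii, curves = curves, peak_r = peak_r)
}

#' Photobleaching curve from a time-lapse
#'
#' The per-frame L2 norm of the noisy data is normalized to its maximum
#' over frames; when a prediction stack is supplied, this vector rescales
#' the max-normalized predictions (restoring the bleaching trend that
#' per-frame normalization of predictions would hide).  Reports the
#' per-frame mean intensity trace and the half-signal frame (first frame
#' at which the trace falls to half its maximum, linearly interpolated).
#'
#' @param noisy 3D array (y, x, frame) of raw acquisitions, >= 2 frames.
#' @param prediction Optional same-shape stack of restored frames.
#' @param smooth Odd window of the centered running mean applied to the
#'   trace before locating the half-signal crossing (the raw trace of a
#'   shot-noise-limited series jitters by a few percent per frame; the
#'   reported `trace` stays unsmoothed). 1 disables smoothing.
#' @return An object of class `bleach_curve`: `frame`, `l2_norm`
#'   (normalized), `trace` (per-frame mean intensity of the analyzed
#'   stack), `half_frame`.
#' @export
bleach_curve <- function(noisy, prediction = NULL, smooth = 5L) {
  d <- dim(noisy)
  if (length(d) != 3L || d[3] < 2L)
    stop("need a stack with at least 2 frames", call. = FALSE)
  if (!is.null(prediction)) check_same_shape(noisy, prediction)
  norms <- apply(noisy, 3L, function(f) sqrt(sum(f^2)))
  nvec <- norms / max(norms)
  if (is.null(prediction)) {
    trace <- apply(noisy, 3L, mean)
  } else {
    pmax_ <- max(prediction)
    predn <- prediction / pmax_
    trace <- vapply(seq_len(d[3]),
                    function(t) mean(predn[, , t]) * nvec[t], numeric(1))
  }
  sm <- trace
  if (smooth > 1L) {
    r <- (as.integer(smooth) - 1L) %/% 2L
    nfr <- length(trace)
    # symmetric window, shrunk near the edges: an asymmetric window would
    # bias the anchor frame of a decaying trace
    sm <- vapply(seq_len(nfr), function(t) {
      rt <- min(r, t - 1L, nfr - t)
      mean(trace[(t - rt):(t + rt)])
    }, numeric(1))
  }
  tn <- sm / max(sm)
  half <- NA_real_
  below <- which(tn <= 0.5)
  below <- below[below > which.max(tn)]
  if (length(below) > 0) {
    i <- below[1]
    t0 <- i - 1L
    half <- t0 + (tn[t0] - 0.5) / (tn[t0] - tn[i])
  }
  structure(list(frame = seq_len(d[3]), l2_norm = nvec, trace = trace,
                 half_frame = half),
            class = "bleach_curve")
}

#' @export
print.bleach_curve <- function(x, ...) {
  cat(sprintf("<bleach_curve> %d frames, half-signal frame: %s\n",
              length(x$frame),
              if (is.na(x$half_frame)) "not reached"
              else sprintf("%.1f", x$half_frame)))
  invisible(x)
}

#' Error map between prediction and ground truth
#'
#' @param prediction,gt Images of identical shape.
#' @param signed Keep the sign of the difference (default: absolute).
#' @return Difference image.
#' @export
error_map <- function(prediction, gt, signed = FALSE) {
  check_same_shape(prediction, gt)
  if (signed) prediction - gt else abs(prediction - gt)
}

#' Metrics report over a set of images
#'
#' Computes PSNR, NMSE and MS-SSIM per image pair and aggregates
#' mean and standard deviation across images.
#'
#' @param references,tests Lists of image arrays (pairwise).
#' @param scales MS-SSIM scales (reduce for small images).
#' @return An object of class `metrics_report` with a per-image data
#'   frame and an `aggregate` list of mean/sd per metric.
#' @export
metrics_report <- function(references, tests, scales = 5L) {
  stopifnot(length(references) == length(tests), length(tests) > 0)
  rows <- lapply(seq_along(tests), function(i) {
    data.frame(image = i,
               psnr = psnr(references[[i]], tests[[i]]),
               nmse = nmse(references[[i]], tests[[i]]),
               ms_ssim = ms_ssim(references[[i]], tests[[i]], scales = scales))
  })
  per_image <- do.call(rbind, rows)
  agg <- lapply(per_image[c("psnr", "nmse", "ms_ssim")],
                function(v) c(mean = mean(v), sd = stats::sd(v)))
  structure(list(per_image = per_image, aggregate = agg),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf("<metrics_report> n = %d images\n", nrow(x$per_image)))
  cat(sprintf("  PSNR    %6.2f +/- %.2f dB\n", a$psnr["mean"], a$psnr["sd"]))
  cat(sprintf("  NMSE    %6.4f +/- %.4f\n", a$nmse["mean"], a$nmse["sd"]))
  cat(sprintf("  MS-SSIM %6.4f +/- %.4f\n", a$ms_ssim["mean"], a$ms_ssim["sd"]))
  invisible(x)
}
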