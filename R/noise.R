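# Semi-synthetic training data: Poisson noise calibration.
#
# When only high-SNR acquisitions exist, noisy training counterparts are
# synthesized by scaling the high-SNR image with a coefficient lambda and
# drawing a Poisson count at each pixel.  Lambda is calibrated so the
# histogram of the synthetic image matches that of a real fast-STED image
# (MSE between max-normalized histograms with the first bin discarded).

#' Poisson-corrupt a high-SNR image
#'
#' Each pixel value `p` is replaced by a Poisson draw with mean
#' `lam * p`; zeros stay zero and the draw is deterministic under `seed`.
#'
#' @param img Non-negative image array.
#' @param lam Positive scaling coefficient lambda.
#' @param seed Integer seed (or `NULL`).
#' @return Synthetic noisy count array, same shape.
#' @export
poissonize <- function(img, lam, seed = NULL) {
  if (lam <= 0) stop("lam must be positive", call. = FALSE)
  neg <- which(img < 0)
  if (length(neg) > 0) {
    stop(sprintf("image contains negative pixel(s); first offending index: %d",
                 neg[1]), call. = FALSE)
  }
  counts <- with_seed(seed, stats::rpois(length(img), lam * as.vector(img)))
  out <- array(as.numeric(counts), dim(img) %||% length(img))
  if (is.null(dim(img))) out <- as.vector(out)
  out
}

# Histogram over a common bin grid starting at 0 (bin j = [(j-1)*bw, j*bw)).
count_histogram <- function(x, bin_width, n_bins) {
  tabulate(pmin(floor(as.vector(x) / bin_width), n_bins - 1L) + 1L,
           nbins = n_bins)
}

#' Histogram MSE between two images
#'
#' Both images are binned on a common grid spanning `[0, max(both)]`; the
#' first bin is discarded, each histogram is normalized to its own
#' maximum, and the mean squared error between the two is returned.
#' Symmetric in its arguments.
#'
#' @param img_a,img_b Non-negative images (count-valued in typical use).
#' @param bin_width Histogram bin width in count units (default 1, since
#'   Poisson counts are integers).
#' @return Scalar MSE between the normalized histograms.
#' @export
histogram_distance <- function(img_a, img_b, bin_width = 1) {
  if (any(img_a < 0) || any(img_b < 0))
    stop("images must be non-negative", call. = FALSE)
  stopifnot(bin_width > 0)
  top <- max(img_a, img_b)
  n_bins <- max(2L, floor(top / bin_width) + 1L)
  ha <- count_histogram(img_a, bin_width, n_bins)[-1L]
  hb <- count_histogram(img_b, bin_width, n_bins)[-1L]
  if (length(ha) == 0L || (max(ha) == 0 && max(hb) == 0))
    stop("histograms are empty after discarding the first bin", call. = FALSE)
  if (max(ha) == 0 || max(hb) == 0)
    stop("one histogram is empty after discarding the first bin", call. = FALSE)
  ha <- ha / max(ha)
  hb <- hb / max(hb)
  mean((ha - hb)^2)
}

#' Calibrate the Poisson scaling coefficient lambda
#'
#' For each candidate lambda a fresh synthetic noisy image is drawn from
#' the high-SNR image and compared to the reference fast-STED image by
#' [histogram_distance()]; the MSE-minimizing lambda is kept.  The whole
#' search is repeated `n_repeats` times (default 5) and the mean of the
#' per-repeat estimates is returned.  The default search grid is 25
#' log-spaced points spanning one decade either side of the count-ratio
#' initial guess `mean(reference)/mean(high_snr)`, refined once on a finer
#' grid around the coarse minimum.
#'
#' @param high_snr High-SNR (ground-truth-quality) image.
#' @param reference Real noisy image acquired at the target dwell time.
#' @param lambda_grid Optional explicit candidate grid.
#' @param n_repeats Number of independent repeats averaged.
#' @param bin_width Histogram bin width.
#' @param seed Integer seed.
#' @param refine Refine around the coarse minimum on an 11-point grid.
#' @return An object of class `noise_calibration` with fields `lam`,
#'   `per_repeat_lams`, `fit_mse`, `n_repeats`, `bin_width`.
#' @export
fit_lambda <- function(high_snr, reference, lambda_grid = NULL,
                       n_repeats = 5L, bin_width = 1, seed = NULL,
                       refine = TRUE) {
  stopifnot(n_repeats >= 1L)
  if (mean(high_snr) <= 0) stop("high_snr image is empty", call. = FALSE)
  guess <- mean(reference) / mean(high_snr)
  if (is.null(lambda_grid)) {
    lambda_grid <- exp(seq(log(guess / 10), log(guess * 10), length.out = 25L))
  }
  lambda_grid <- sort(lambda_grid)
  seeds <- child_seeds(seed, n_repeats)
  one_repeat <- function(rseed) {
    with_seed(rseed, {
      mse <- vapply(lambda_grid, function(l)
        histogram_distance(poissonize(high_snr, l), reference, bin_width),
        numeric(1))
      i <- which.min(mse)
      if (i == 1L || i == length(lambda_grid)) {
        warning("lambda minimum attained at the search-grid boundary; ",
                "consider a wider lambda_grid", call. = FALSE)
      }
      best <- lambda_grid[i]
      best_mse <- mse[i]
      if (refine && i > 1L && i < length(lambda_grid)) {
        fine <- seq(lambda_grid[i - 1L], lambda_grid[i + 1L], length.out = 11L)
        fmse <- vapply(fine, function(l)
          histogram_distance(poissonize(high_snr, l), reference, bin_width),
          numeric(1))
        j <- which.min(fmse)
        best <- fine[j]
        best_mse <- fmse[j]
      }
      c(best, best_mse)
    })
  }
  res <- vapply(seeds, one_repeat, numeric(2))
  structure(list(lam = mean(res[1, ]),
                 per_repeat_lams = res[1, ],
                 fit_mse = mean(res[2, ]),
                 n_repeats = as.integer(n_repeats),
                 bin_width = bin_width,
                 initial_guess = guess),
            class = "noise_calibration")
}

#' @export
print.noise_calibration <- function(x, ...) {
  cat(sprintf("<noise_calibration> lambda = %.4g (mean of %d repeats: %s)\n",
              x$lam, x$n_repeats,
              paste(signif(x$per_repeat_lams, 3), collapse = ", ")))
  cat(sprintf("  histogram MSE at fit: %.3g\n", x$fit_mse))
  invisible(x)
}

#' Persist / load a noise calibration as JSON
#' @param calib A `noise_calibration`.
#' @param path JSON file path.
#' @return The calibration (invisibly for write).
#' @export
write_calibration <- function(calib, path) {
  jsonlite::write_json(unclass(calib), path, auto_unbox = TRUE, digits = NA)
  invisible(calib)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "noise_calibration")
}
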