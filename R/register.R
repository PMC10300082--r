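# Rigid xy-drift correction between noisy and ground-truth images.
#
# The drift is the lag maximizing the circular (wrap-around) normalized
# cross-correlation, computed in the Fourier domain.  No windowing is
# applied; after shifting, vacated margins are zero-filled and reported as
# an invalid-margin mask rather than wrapped, because training patches
# must not contain wrapped content.

#' Estimate rigid drift between two images
#'
#' Returns the integer lag `d` maximizing the zero-mean normalized
#' cross-correlation, i.e. the `d` for which `b` best matches `a`
#' translated by `d` (so `estimate_drift(a, roll(a, d)) == d`).
#' Optional 3-point parabolic sub-pixel refinement per axis (off by
#' default; integer maxima match the plain Fourier method).
#'
#' @param img_a,img_b Arrays of identical shape with nonzero variance.
#' @param subpixel Refine the peak to sub-pixel precision.
#' @return An object of class `drift`: fields `shift` (per-axis lag),
#'   `dy`, `dx` (and `dz` for 3D) and `peak_value` (normalized correlation
#'   at the maximum, in `[-1, 1]`).
#' @export
estimate_drift <- function(img_a, img_b, subpixel = FALSE) {
  check_same_shape(img_a, img_b)
  if (stats::sd(img_a) == 0 || stats::sd(img_b) == 0)
    stop("constant image: correlation undefined", call. = FALSE)
  a0 <- img_a - mean(img_a)
  b0 <- img_b - mean(img_b)
  n <- dim(a0)
  cc <- Re(stats::fft(Conj(stats::fft(a0)) * stats::fft(b0), inverse = TRUE)) /
    length(a0)
  denom <- sqrt(sum(a0^2) * sum(b0^2))
  ccn <- cc / denom
  peak <- which.max(ccn)
  coord <- arrayInd(peak, n)[1, ]
  lag <- coord - 1L
  lag <- as.integer(ifelse(lag > n %/% 2L, lag - n, lag))
  shift <- lag                      # integer lags unless refined
  if (subpixel) {
    shift <- as.numeric(shift)
    for (ax in seq_along(n)) {
      get_cc <- function(off) {
        co <- coord
        co[ax] <- ((co[ax] - 1L + off) %% n[ax]) + 1L
        ccn[matrix(co, 1L)]
      }
      ym <- get_cc(-1L); y0 <- get_cc(0L); yp <- get_cc(1L)
      den <- ym - 2 * y0 + yp
      if (den < 0) shift[ax] <- shift[ax] + 0.5 * (ym - yp) / den
    }
  }
  out <- list(shift = shift, dy = shift[1], dx = shift[2],
              peak_value = ccn[peak])
  if (length(n) == 3L) out$dz <- shift[3]
  structure(out, class = "drift")
}

#' @export
print.drift <- function(x, ...) {
  cat(sprintf("<drift> shift = (%s), peak correlation %.3f\n",
              paste(signif(x$shift, 4), collapse = ", "), x$peak_value))
  invisible(x)
}

#' Translate an image to undo an estimated drift
#'
#' The image is translated by `-drift` so that the pair aligns; vacated
#' borders are zero-filled and recorded in a logical `valid_mask`
#' attribute (FALSE over the invalid margin, whose width equals the
#' absolute drift on each shifted edge).
#'
#' @param img Image array.
#' @param drift A `drift` object or integer lag vector.
#' @return Shifted array with a `valid_mask` attribute.
#' @export
apply_drift <- function(img, drift) {
  d <- if (inherits(drift, "drift")) drift$shift else drift
  d <- round(d)
  n <- dim(img)
  stopifnot(length(d) == length(n))
  if (any(abs(d) > n %/% 2L))
    stop("drift exceeds half the image extent", call. = FALSE)
  out <- shift_zero(img, -d)
  mask <- array(TRUE, n)
  for (ax in seq_along(n)) {
    if (d[ax] == 0) next
    bad <- if (d[ax] > 0) (n[ax] - d[ax] + 1L):n[ax] else seq_len(-d[ax])
    idx <- lapply(n, seq_len)
    idx[[ax]] <- bad
    mask <- do.call(`[<-`, c(list(mask), idx, list(value = FALSE)))
  }
  attr(out, "valid_mask") <- mask
  out
}

#' Register a noisy/ground-truth pair (or stack)
#'
#' For 2D inputs the single drift is estimated and removed from the noisy
#' member; for stacks (3rd dimension = frames) the drift is estimated per
#' frame pair independently.
#'
#' @param noisy,gt Image or stack arrays of identical shape.
#' @param subpixel Passed to [estimate_drift()] (estimation only; the
#'   applied correction is integer).
#' @return List with `noisy` (aligned), `gt`, and a `report` data frame
#'   (frame, dy, dx, peak).
#' @export
register_pair <- function(noisy, gt, subpixel = FALSE) {
  check_same_shape(noisy, gt)
  nd <- length(dim(noisy))
  if (nd == 2L) {
    dr <- estimate_drift(gt, noisy, subpixel = subpixel)
    aligned <- apply_drift(noisy, dr)
    report <- data.frame(frame = 1L, dy = dr$dy, dx = dr$dx,
                         peak = dr$peak_value)
    return(list(noisy = aligned, gt = gt, report = report))
  }
  if (nd != 3L) stop("expected a 2D image or a 3D stack", call. = FALSE)
  nf <- dim(noisy)[3]
  out <- noisy
  rows <- vector("list", nf)
  for (f in seq_len(nf)) {
    dr <- estimate_drift(gt[, , f], noisy[, , f], subpixel = subpixel)
    out[, , f] <- apply_drift(noisy[, , f], dr)
    rows[[f]] <- data.frame(frame = f, dy = dr$dy, dx = dr$dx,
                            peak = dr$peak_value)
  }
  list(noisy = out, gt = gt, report = do.call(rbind, rows))
}
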