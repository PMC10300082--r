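# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state so
#' that seeded operations do not perturb the global random stream.
#' A `NULL` seed evaluates `code` under the current stream.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream of child seeds from one seed (kept below 2^31).
child_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  with_seed(seed, as.list(sample.int(.Machine$integer.max - 1L, n)))
}

# Shift an array along one axis by t pixels, zero-filling vacated entries.
shift_axis_zero <- function(a, t, axis) {
  d <- dim(a)
  n <- d[axis]
  out <- array(0, d)
  if (abs(t) >= n) return(out)
  src <- seq_len(n - abs(t))
  if (t >= 0) {
    out_idx <- src + t
    in_idx <- src
  } else {
    out_idx <- src
    in_idx <- src - t
  }
  args_in <- lapply(d, seq_len)
  args_in[[axis]] <- in_idx
  args_out <- lapply(d, seq_len)
  args_out[[axis]] <- out_idx
  piece <- do.call(`[`, c(list(a), args_in, list(drop = FALSE)))
  do.call(`[<-`, c(list(out), args_out, list(value = piece)))
}

# Translate an array by an integer offset vector (zero fill).
shift_zero <- function(a, t) {
  out <- a
  for (ax in seq_along(t)) {
    if (t[ax] != 0) out <- shift_axis_zero(out, t[ax], ax)
  }
  out
}

# Circular shift: out[i] = a[i - d], i.e. content moves by +d.
roll <- function(a, d) {
  n <- dim(a)
  stopifnot(length(d) == length(n))
  idx <- lapply(seq_along(n), function(k) ((seq_len(n[k]) - 1L - d[k]) %% n[k]) + 1L)
  out <- do.call(`[`, c(list(a), idx, list(drop = FALSE)))
  dim(out) <- n
  out
}

# Normalized 1D Gaussian kernel, truncated at 4 sigma.
gaussian_kernel_1d <- function(sigma, truncate = 4) {
  r <- max(1L, ceiling(truncate * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable convolution of an array with one 1D kernel per axis (zero padding).
separable_convolve <- function(a, kernels) {
  d <- dim(a)
  stopifnot(length(kernels) == length(d))
  out <- a
  for (ax in seq_along(d)) {
    kern <- kernels[[ax]]
    if (length(kern) == 1L) {
      out <- out * kern
      next
    }
    r <- (length(kern) - 1L) / 2L
    acc <- array(0, d)
    for (t in (-r):r) {
      w <- kern[t + r + 1L]
      if (w == 0) next
      acc <- acc + w * shift_axis_zero(out, t, ax)
    }
    out <- acc
  }
  out
}

# Sample an image at fractional positions by bilinear interpolation.
# pts: n x 2 matrix of (row, col) positions, 1-based.
bilinear_sample <- function(img, pts) {
  d <- dim(img)
  y <- pmin(pmax(pts[, 1], 1), d[1])
  x <- pmin(pmax(pts[, 2], 1), d[2])
  y0 <- pmin(floor(y), d[1] - 1)
  x0 <- pmin(floor(x), d[2] - 1)
  fy <- y - y0
  fx <- x - x0
  v00 <- img[cbind(y0, x0)]
  v10 <- img[cbind(y0 + 1, x0)]
  v01 <- img[cbind(y0, x0 + 1)]
  v11 <- img[cbind(y0 + 1, x0 + 1)]
  v00 * (1 - fy) * (1 - fx) + v10 * fy * (1 - fx) +
    v01 * (1 - fy) * fx + v11 * fy * fx
}

check_same_shape <- function(a, b, what = "images") {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("%s must have identical shapes (got %s vs %s)",
                 what, paste(dim(a), collapse = "x"),
                 paste(dim(b), collapse = "x")), call. = FALSE)
  }
  invisible(TRUE)
}
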