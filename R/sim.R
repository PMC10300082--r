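# Synthetic STED image simulator.
#
# Phantoms emulate the targets STED is typically pointed at: filamentous
# structures (microtubule-like), puncta (histone/nuclear marker-like) and
# hollow tubes (mitochondria-like, imaged as shells).  Optics are an
# effective Gaussian PSF whose FWHM follows the STED scaling law
# d = d_conf / sqrt(1 + P/Psat); acquisition is per-pixel Poisson shot
# noise whose expectation scales linearly with the pixel dwell time.

#' Create a synthetic phantom
#'
#' Generates analytic structure primitives (curves, points, tube axes)
#' fully inside the grid, deterministically under `seed`.  Pass
#' `structures` to place primitives explicitly; each is a list with a
#' `type` of `"point"` (fields `pos`, `amplitude`), `"curve"` (`points`
#' control-point matrix, `amplitude`) or `"tube"` (`points`, `radius_px`,
#' `amplitude`).
#'
#' @param kind Structure class: filaments, puncta or hollow tubes.
#' @param shape Integer grid dimensions, length 2 (y, x) or 3 (y, x, z).
#' @param pixel_size Pixel size in nm.
#' @param n_structures Number of primitives (default scales with area).
#' @param seed Integer seed making structure placement reproducible.
#' @param margin Fraction of each extent kept clear of structure control
#'   points so primitives stay inside the grid.
#' @param amplitude Base intensity of a structure (arbitrary units).
#' @param tube_radius_nm Shell radius for `hollow_tubes`.
#' @param structures Optional explicit primitive list (overrides generation).
#' @return An object of class `phantom`.
#' @export
#' @examples
#' ph <- phantom("filaments", shape = c(128, 128), seed = 1)
#' img <- render_phantom(ph)
phantom <- function(kind = c("filaments", "puncta", "hollow_tubes"),
                    shape = c(512L, 512L), pixel_size = 20,
                    n_structures = NULL, seed = 1L, margin = 0.04,
                    amplitude = 1, tube_radius_nm = 150,
                    structures = NULL) {
  kind <- match.arg(kind)
  shape <- as.integer(shape)
  stopifnot(length(shape) %in% c(2L, 3L), all(shape > 0L), pixel_size > 0)
  d <- length(shape)
  if (is.null(structures)) {
    area_scale <- prod(shape[1:2]) / (512 * 512)
    n <- n_structures %||% switch(kind,
      filaments = max(3L, round(10 * area_scale)),
      puncta = max(10L, round(180 * area_scale)),
      hollow_tubes = max(2L, round(5 * area_scale)))
    lo <- pmax(1 + margin * shape, 1.5)
    hi <- pmin(shape - margin * shape, shape - 0.5)
    structures <- with_seed(seed, {
      lapply(seq_len(n), function(i) {
        amp <- amplitude * stats::runif(1, 0.5, 1)
        if (kind == "puncta") {
          list(type = "point",
               pos = stats::runif(d, lo, hi),
               amplitude = amp)
        } else {
          npts <- sample(4:7, 1)
          start <- stats::runif(d, lo, hi)
          steps <- matrix(stats::rnorm(npts * d, sd = rep(shape / 5, each = npts)),
                          npts, d)
          pts <- apply(rbind(start, steps), 2, cumsum)
          pts <- pmin(pmax(pts, rep(lo, each = npts + 1)),
                      rep(hi, each = npts + 1))
          if (kind == "filaments") {
            list(type = "curve", points = pts, amplitude = amp)
          } else {
            list(type = "tube", points = pts,
                 radius_px = tube_radius_nm / pixel_size, amplitude = amp)
          }
        }
      })
    })
  }
  structure(list(kind = kind, shape = shape, pixel_size = pixel_size,
                 structures = structures, seed = as.integer(seed)),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %s, %s grid, %g nm/px, %d structures\n",
              x$kind, paste(x$shape, collapse = "x"), x$pixel_size,
              length(x$structures)))
  invisible(x)
}

# Centripetal-free uniform Catmull-Rom spline through control points.
catmull_rom <- function(pts, step = 0.25) {
  if (nrow(pts) == 1L) return(pts)
  if (nrow(pts) == 2L) {
    n <- max(2L, ceiling(sqrt(sum((pts[2, ] - pts[1, ])^2)) / step))
    t <- seq(0, 1, length.out = n)
    return(outer(1 - t, pts[1, ]) + outer(t, pts[2, ]))
  }
  P <- rbind(pts[1, ], pts, pts[nrow(pts), ])  # duplicated endpoints
  segs <- list()
  for (i in seq_len(nrow(pts) - 1L)) {
    p0 <- P[i, ]; p1 <- P[i + 1, ]; p2 <- P[i + 2, ]; p3 <- P[i + 3, ]
    len <- sqrt(sum((p2 - p1)^2))
    n <- max(2L, ceiling(len / step))
    t <- seq(0, 1, length.out = n)
    t2 <- t * t; t3 <- t2 * t
    seg <- 0.5 * (outer(2 * t3 - 3 * t2 + 1, 2 * p1) +
                  outer(t3 - 2 * t2 + t, p2 - p0) +
                  outer(-2 * t3 + 3 * t2, 2 * p2) +
                  outer(t3 - t2, p3 - p1))
    segs[[i]] <- if (i == 1L) seg else seg[-1L, , drop = FALSE]
  }
  do.call(rbind, segs)
}

# Deposit point masses at sub-pixel positions with multilinear weights.
deposit_points <- function(grid, pts, w) {
  d <- dim(grid)
  nd <- length(d)
  if (is.null(nrow(pts))) pts <- matrix(pts, 1L)
  inside <- rep(TRUE, nrow(pts))
  for (ax in seq_len(nd)) inside <- inside & pts[, ax] >= 1 & pts[, ax] <= d[ax]
  if (!all(inside)) {
    stop("structure primitive extends outside the representable grid",
         call. = FALSE)
  }
  base <- pmin(floor(pts), matrix(rep(d - 1L, each = nrow(pts)), ncol = nd))
  base <- pmax(base, 1)
  frac <- pts - base
  strides <- cumprod(c(1, d[-nd]))
  corners <- as.matrix(expand.grid(rep(list(0:1), nd), KEEP.OUT.ATTRS = FALSE))
  gv <- as.vector(grid)
  for (ci in seq_len(nrow(corners))) {
    off <- corners[ci, ]
    wt <- w
    for (ax in seq_len(nd)) {
      wt <- wt * if (off[ax] == 1) frac[, ax] else (1 - frac[, ax])
    }
    lin <- as.integer(1 + (base - 1 + rep(off, each = nrow(base))) %*% strides)
    agg <- rowsum(wt, lin)
    gv[as.integer(rownames(agg))] <- gv[as.integer(rownames(agg))] + agg[, 1]
  }
  array(gv, d)
}

# Orthonormal vectors spanning the plane normal to a 3D tangent.
normal_frame <- function(tg) {
  tg <- tg / sqrt(sum(tg^2))
  a <- if (abs(tg[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  n1 <- a - sum(a * tg) * tg
  n1 <- n1 / sqrt(sum(n1^2))
  n2 <- c(tg[2] * n1[3] - tg[3] * n1[2],
          tg[3] * n1[1] - tg[1] * n1[3],
          tg[1] * n1[2] - tg[2] * n1[1])
  list(n1 = n1, n2 = n2)
}

#' Render a phantom into a noiseless intensity grid
#'
#' Curves are rasterized from a Catmull-Rom spline with anti-aliased
#' sub-pixel deposition (intensity per unit arc length is constant); tubes
#' deposit on a shell at the tube radius around the axis.  Rendering is
#' purely deterministic; identical phantoms give bitwise-identical grids.
#'
#' @param ph A [phantom()].
#' @return Non-negative array of shape `ph$shape` with `pixel_size` attribute.
#' @export
render_phantom <- function(ph) {
  stopifnot(inherits(ph, "phantom"))
  grid <- array(0, ph$shape)
  d <- length(ph$shape)
  for (s in ph$structures) {
    if (s$type == "point") {
      grid <- deposit_points(grid, matrix(s$pos, 1L), s$amplitude)
    } else if (s$type == "curve") {
      sm <- catmull_rom(s$points, step = 0.25)
      # Catmull-Rom segments can overshoot the control-point hull; clip
      # samples at the grid so generated filaments stay representable
      sm <- pmin(pmax(sm, 1), rep(ph$shape, each = nrow(sm)))
      seg <- sqrt(rowSums((sm - sm[c(1, seq_len(nrow(sm) - 1L)), , drop = FALSE])^2))
      seg[1] <- seg[2]
      grid <- deposit_points(grid, sm, s$amplitude * seg)
    } else if (s$type == "tube") {
      sm <- catmull_rom(s$points, step = 0.25)
      seg <- sqrt(rowSums((sm - sm[c(1, seq_len(nrow(sm) - 1L)), , drop = FALSE])^2))
      seg[1] <- seg[2]
      tangents <- sm[c(2:nrow(sm), nrow(sm)), , drop = FALSE] -
        sm[c(1, seq_len(nrow(sm) - 1L)), , drop = FALSE]
      r <- s$radius_px
      if (d == 2L) {
        tn <- tangents / pmax(sqrt(rowSums(tangents^2)), 1e-9)
        nrm <- cbind(-tn[, 2], tn[, 1])
        pts <- rbind(sm + r * nrm, sm - r * nrm)
        pts <- pmin(pmax(pts, 1), rep(ph$shape, each = nrow(pts)))
        grid <- deposit_points(grid, pts, s$amplitude * c(seg, seg) / 2)
      } else {
        nang <- 16L
        ang <- seq(0, 2 * pi, length.out = nang + 1L)[-(nang + 1L)]
        allpts <- vector("list", nrow(sm))
        for (i in seq_len(nrow(sm))) {
          fr <- normal_frame(tangents[i, ] + 1e-9)
          ring <- matrix(rep(sm[i, ], each = nang), nang) +
            r * (outer(cos(ang), fr$n1) + outer(sin(ang), fr$n2))
          allpts[[i]] <- ring
        }
        pts <- do.call(rbind, allpts)
        pts <- pmin(pmax(pts, 1), rep(ph$shape, each = nrow(pts)))
        grid <- deposit_points(grid, pts, s$amplitude * rep(seg / nang, each = nang))
      }
    } else {
      stop("unknown structure type: ", s$type, call. = FALSE)
    }
  }
  attr(grid, "pixel_size") <- ph$pixel_size
  grid
}

#' STED optics model
#'
#' The effective PSF is an isotropic Gaussian whose lateral FWHM follows
#' the STED resolution scaling law
#' \eqn{d = d_{conf} / \sqrt{1 + P/P_{sat}}}: raising the depletion power
#' fraction `sted_power_fraction` sharpens the PSF below the confocal FWHM.
#'
#' @param confocal_fwhm Confocal (zero-depletion) FWHM in nm.
#' @param sted_power_fraction Depletion power as a fraction of maximum, in
#'   `[0, 1]`.
#' @param saturation_power_fraction Saturation power on the same fractional
#'   scale (> 0).
#' @param axial_fwhm_factor For 3D volumes, axial FWHM as a multiple of the
#'   lateral FWHM (z-STED depletes less along the axis).
#' @return An object of class `optics_model`.
#' @export
optics_model <- function(confocal_fwhm = 240,
                         sted_power_fraction = 0.7,
                         saturation_power_fraction = 0.05,
                         axial_fwhm_factor = 2.5) {
  if (sted_power_fraction < 0)
    stop("sted_power_fraction must be non-negative", call. = FALSE)
  if (saturation_power_fraction <= 0)
    stop("saturation_power_fraction must be positive", call. = FALSE)
  stopifnot(confocal_fwhm > 0, axial_fwhm_factor > 0)
  structure(list(confocal_fwhm = confocal_fwhm,
                 sted_power_fraction = sted_power_fraction,
                 saturation_power_fraction = saturation_power_fraction,
                 axial_fwhm_factor = axial_fwhm_factor,
                 psf_kind = "gaussian"),
            class = "optics_model")
}

#' Effective PSF width under STED depletion
#'
#' @param optics An [optics_model()].
#' @return Effective lateral FWHM in nm,
#'   `confocal_fwhm / sqrt(1 + P/Psat)`.
#' @export
#' @examples
#' effective_fwhm(optics_model(240, sted_power_fraction = 0.75,
#'                             saturation_power_fraction = 0.05))  # 60 nm
effective_fwhm <- function(optics) {
  stopifnot(inherits(optics, "optics_model"))
  optics$confocal_fwhm /
    sqrt(1 + optics$sted_power_fraction / optics$saturation_power_fraction)
}

#' Blur an intensity grid with the effective STED PSF
#'
#' Convolution with a normalized (unit-sum) Gaussian kernel of the
#' effective FWHM, so total intensity is conserved for structures away
#' from the borders.  In 3D the axial FWHM is
#' `axial_fwhm_factor` times the lateral one.
#'
#' @param img Non-negative intensity array (2D or 3D).
#' @param optics An [optics_model()].
#' @param pixel_size Lateral pixel size in nm (default taken from the
#'   rendered phantom's attribute).
#' @return Blurred array, same shape.
#' @export
psf_blur <- function(img, optics, pixel_size = attr(img, "pixel_size")) {
  stopifnot(inherits(optics, "optics_model"))
  if (is.null(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be positive", call. = FALSE)
  d <- dim(img) %||% stop("img must be an array", call. = FALSE)
  fwhm <- effective_fwhm(optics)
  fwhm_px <- fwhm / pixel_size
  if (fwhm_px < 1) {
    warning("effective FWHM below 1 pixel; kernel clamped to 1 pixel width")
    fwhm_px <- 1
  }
  sig <- fwhm_px / (2 * sqrt(2 * log(2)))
  kerns <- rep(list(gaussian_kernel_1d(sig)), length(d))
  if (length(d) == 3L) {
    sig_z <- sig * optics$axial_fwhm_factor
    kerns[[3]] <- gaussian_kernel_1d(sig_z)
  }
  out <- separable_convolve(img, kerns)
  attr(out, "pixel_size") <- pixel_size
  out
}

#' Detection / acquisition model
#'
#' Expected photon counts per pixel are
#' `dwell_time * (brightness * intensity + background)`: they scale
#' linearly with the pixel dwell time, so short dwell times give few
#' photons and a poor SNR.
#'
#' @param dwell_time Pixel dwell time in microseconds.
#' @param brightness Expected photons per unit intensity per microsecond.
#' @param background Expected background photons per pixel per microsecond.
#' @param seed Default seed for [acquire()].
#' @return An object of class `acquisition_model`.
#' @export
acquisition_model <- function(dwell_time, brightness = 40, background = 0.5,
                              seed = NULL) {
  stopifnot(dwell_time >= 0, brightness >= 0, background >= 0)
  structure(list(dwell_time = dwell_time, brightness = brightness,
                 background = background, seed = seed),
            class = "acquisition_model")
}

#' Acquire a noisy image from a blurred intensity grid
#'
#' Each pixel is an independent Poisson draw with the expectation set by
#' the acquisition model; deterministic under `seed`.  Counts are returned
#' as doubles so one pixel type flows through the whole pipeline.
#'
#' @param img Non-negative (blurred) intensity array.
#' @param acq An [acquisition_model()].
#' @param seed Seed (defaults to the model's).
#' @return Count array of the same shape, with `dwell_time` attribute.
#' @export
acquire <- function(img, acq, seed = acq$seed) {
  stopifnot(inherits(acq, "acquisition_model"))
  if (any(img < 0)) stop("intensity grid must be non-negative", call. = FALSE)
  lam <- acq$dwell_time * (acq$brightness * img + acq$background)
  if (any(!is.finite(lam))) stop("expected counts must be finite", call. = FALSE)
  counts <- with_seed(seed, stats::rpois(length(lam), as.vector(lam)))
  out <- array(as.numeric(counts), dim(img))
  attr(out, "pixel_size") <- attr(img, "pixel_size")
  attr(out, "dwell_time") <- acq$dwell_time
  out
}

#' Simulate a registered training pair
#'
#' One phantom is rendered and blurred once; two acquisitions of the same
#' blurred ground truth are drawn — a fast, low-SNR member at `dwell_fast`
#' and a slow, high-SNR member at `dwell_slow` (defaults 0.072 and 2.3 us,
#' a >30-fold exposure contrast).  The noiseless blurred grid is retained
#' for oracle metrics.
#'
#' @param ph A [phantom()].
#' @param optics An [optics_model()].
#' @param dwell_fast,dwell_slow Pixel dwell times in microseconds
#'   (`dwell_fast < dwell_slow`).
#' @param brightness,background Acquisition-model rates (per us).
#' @param seed Integer seed controlling both acquisitions.
#' @return A `training_pair`: list with `noisy`, `gt`, `truth` (noiseless
#'   blurred intensity) and metadata.
#' @export
simulate_pair <- function(ph, optics = optics_model(),
                          dwell_fast = 0.072, dwell_slow = 2.3,
                          brightness = 40, background = 0.5, seed = 1L) {
  if (!(dwell_fast < dwell_slow))
    stop("dwell_fast must be smaller than dwell_slow", call. = FALSE)
  truth <- psf_blur(render_phantom(ph), optics, ph$pixel_size)
  seeds <- child_seeds(seed, 2L)
  noisy <- acquire(truth, acquisition_model(dwell_fast, brightness, background),
                   seed = seeds[[1]])
  gt <- acquire(truth, acquisition_model(dwell_slow, brightness, background),
                seed = seeds[[2]])
  structure(list(noisy = noisy, gt = gt, truth = truth,
                 dwell_fast = dwell_fast, dwell_slow = dwell_slow,
                 brightness = brightness, background = background,
                 pixel_size = ph$pixel_size, seed = seed),
            class = "training_pair")
}

#' @export
print.training_pair <- function(x, ...) {
  cat(sprintf(
    "<training_pair> %s px, dwell %g / %g us (mean counts %.3g / %.3g)\n",
    paste(dim(x$noisy), collapse = "x"), x$dwell_fast, x$dwell_slow,
    mean(x$noisy), mean(x$gt)))
  invisible(x)
}

#' Simulate a photobleaching time-lapse
#'
#' Frame t is acquired with the fluorophore brightness decayed as
#' `exp(-bleach_rate * dose)` where the cumulative illumination dose is
#' proportional to the dwell time: `dose = dwell_time * (t - 1)`.
#' Background does not bleach.
#'
#' @param ph A [phantom()] (2D).
#' @param optics An [optics_model()].
#' @param acq An [acquisition_model()] fixing dwell time and rates.
#' @param n_frames Number of frames (>= 1).
#' @param bleach_rate Exponential decay constant per unit dose
#'   (per microsecond of per-pixel illumination).
#' @param seed Integer seed.
#' @return Array (y, x, frame) of counts with acquisition attributes.
#' @export
simulate_timelapse <- function(ph, optics, acq, n_frames, bleach_rate = 0,
                               seed = 1L) {
  stopifnot(n_frames >= 1, bleach_rate >= 0)
  truth <- psf_blur(render_phantom(ph), optics, ph$pixel_size)
  seeds <- child_seeds(seed, n_frames)
  out <- array(0, c(dim(truth), n_frames))
  idx <- c(rep(list(quote(expr = )), length(dim(truth))))
  for (t in seq_len(n_frames)) {
    decay <- exp(-bleach_rate * acq$dwell_time * (t - 1))
    frame <- acquire(truth * decay, acq, seed = seeds[[t]])
    if (length(dim(truth)) == 2L) out[, , t] <- frame else out[, , , t] <- frame
  }
  attr(out, "pixel_size") <- ph$pixel_size
  attr(out, "dwell_time") <- acq$dwell_time
  attr(out, "bleach_rate") <- bleach_rate
  out
}
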