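# Training patch preparation: extraction, per-patch max normalization and
# L2-norm content filtering.
#
# Pipeline order is fixed and asserted by tests: patches are cut at
# identical offsets from both pair members, each patch is normalized to
# its own maximum, then the L2 norm of the normalized ground-truth member
# is divided by the dataset maximum norm, and patches below the content
# threshold are discarded.

#' Extract aligned patch pairs from a registered image pair
#'
#' Offsets are either random (up to `max_patches`, seeded) or a regular
#' stride-based tiling; noisy and ground-truth patches are always cut at
#' identical offsets.  When the pair carries a noiseless `truth` grid
#' (simulated data), matching truth patches are kept for oracle metrics.
#'
#' @param pair A `training_pair` or list with `noisy` and `gt` arrays.
#' @param patch_shape Patch dimensions, e.g. `c(256, 256)` (2D) or
#'   `c(160, 160, 16)` (3D).
#' @param stride Tiling stride; `NULL` selects random offsets.
#' @param max_patches Maximum number of patches returned.
#' @param seed Seed for random offsets.
#' @return List of class `patch_pairs`: `noisy`, `gt` (and `truth`) patch
#'   lists plus a `provenance` data frame of offsets.
#' @export
extract_patches <- function(pair, patch_shape = c(256L, 256L), stride = NULL,
                            max_patches = Inf, seed = NULL) {
  noisy <- pair$noisy
  gt <- pair$gt
  check_same_shape(noisy, gt)
  d <- dim(noisy)
  patch_shape <- as.integer(patch_shape)
  if (length(patch_shape) != length(d) || any(patch_shape > d))
    stop("patch_shape must fit inside the image (image ",
         paste(d, collapse = "x"), ", patch ",
         paste(patch_shape, collapse = "x"), ")", call. = FALSE)
  if (!is.null(stride)) {
    offs <- lapply(seq_along(d), function(ax) {
      s <- seq(1L, d[ax] - patch_shape[ax] + 1L, by = stride)
      s
    })
    grid <- as.matrix(expand.grid(offs, KEEP.OUT.ATTRS = FALSE))
    if (nrow(grid) > max_patches) grid <- grid[seq_len(max_patches), , drop = FALSE]
  } else {
    n <- if (is.finite(max_patches)) max_patches else
      prod(pmax(d %/% patch_shape, 1L))
    grid <- with_seed(seed, {
      do.call(cbind, lapply(seq_along(d), function(ax)
        sample.int(d[ax] - patch_shape[ax] + 1L, n, replace = TRUE)))
    })
  }
  cut1 <- function(img, off) {
    idx <- lapply(seq_along(d), function(ax) off[ax]:(off[ax] + patch_shape[ax] - 1L))
    array(do.call(`[`, c(list(img), idx, list(drop = FALSE))), patch_shape)
  }
  res <- list(noisy = vector("list", nrow(grid)),
              gt = vector("list", nrow(grid)))
  has_truth <- !is.null(pair$truth)
  if (has_truth) res$truth <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    res$noisy[[i]] <- cut1(noisy, grid[i, ])
    res$gt[[i]] <- cut1(gt, grid[i, ])
    if (has_truth) res$truth[[i]] <- cut1(pair$truth, grid[i, ])
  }
  res$provenance <- data.frame(patch = seq_len(nrow(grid)), grid)
  names(res$provenance) <- c("patch", paste0("offset", seq_along(d)))
  res$patch_shape <- patch_shape
  class(res) <- "patch_pairs"
  res
}

#' Normalize a patch to its maximum
#'
#' Nonzero patches are divided by their own maximum so the maximum becomes
#' 1; an all-zero patch is returned unchanged with attribute
#' `flagged_empty = TRUE`.
#'
#' @param patch Numeric array.
#' @return Normalized patch (attribute `scale` holds the divisor).
#' @export
normalize_patch <- function(patch) {
  m <- max(patch)
  if (m <= 0) {
    attr(patch, "flagged_empty") <- TRUE
    return(patch)
  }
  out <- patch / m
  attr(out, "scale") <- m
  out
}

#' Filter patches by normalized L2-norm content
#'
#' The L2 norm of each raw ground-truth patch is divided by the maximum
#' norm in the dataset, patches whose normalized norm falls below
#' `threshold` are discarded, and the survivors are max-normalized.  The
#' max-norm patch has normalized norm 1, so at least one patch always
#' survives.  Norms are taken on the raw (pre-normalization) counts:
#' per-patch max normalization rescales the sparse Poisson background of
#' an empty patch up to 1 and can rank it above genuinely structured
#' patches, defeating the filter's purpose of discarding low-information
#' patches.
#'
#' @param patches A `patch_pairs` object from [extract_patches()].
#' @param threshold Content threshold in `[0, 1]`; the working range is
#'   0.2-0.4 and the default is the midpoint 0.3.
#' @return An object of class `patch_set` with normalized surviving pairs,
#'   their normalized norms and provenance.
#' @export
filter_patches <- function(patches, threshold = 0.3) {
  stopifnot(inherits(patches, "patch_pairs"))
  if (threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]", call. = FALSE)
  n <- length(patches$gt)
  if (n == 0L) stop("empty patch set", call. = FALSE)
  norms <- vapply(patches$gt, function(p) sqrt(sum(p^2)), numeric(1))
  nmax <- max(norms)
  if (nmax <= 0) stop("all patches are empty", call. = FALSE)
  nn <- norms / nmax
  keep <- which(nn >= threshold)
  out <- list(noisy = lapply(patches$noisy[keep], normalize_patch),
              gt = lapply(patches$gt[keep], normalize_patch),
              norms = nn[keep], threshold = threshold,
              provenance = patches$provenance[keep, , drop = FALSE],
              patch_shape = patches$patch_shape)
  if (!is.null(patches$truth)) {
    out$truth <- lapply(patches$truth[keep], normalize_patch)
  }
  class(out) <- "patch_set"
  out
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d pairs of %s patches (threshold %.2f)\n",
              length(x$gt), paste(x$patch_shape, collapse = "x"), x$threshold))
  invisible(x)
}

#' @export
length.patch_set <- function(x) length(x$gt)

#' Combine patch sets from several image pairs
#' @param ... `patch_pairs` objects.
#' @return One concatenated `patch_pairs` object.
#' @export
combine_patches <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && !inherits(parts[[1]], "patch_pairs"))
    parts <- parts[[1]]
  out <- list(noisy = do.call(c, lapply(parts, `[[`, "noisy")),
              gt = do.call(c, lapply(parts, `[[`, "gt")))
  truths <- lapply(parts, `[[`, "truth")
  if (!any(vapply(truths, is.null, logical(1))))
    out$truth <- do.call(c, truths)
  prov <- do.call(rbind, lapply(seq_along(parts), function(i) {
    p <- parts[[i]]$provenance
    p$source <- i
    p
  }))
  prov$patch <- seq_len(nrow(prov))
  out$provenance <- prov
  out$patch_shape <- parts[[1]]$patch_shape
  class(out) <- "patch_pairs"
  out
}

#' Train/validation split of a patch set
#'
#' @param ps A `patch_set`.
#' @param val_fraction Fraction of patches held out for validation.
#' @param seed Seed for the split.
#' @return `ps` with an added integer vector `val_idx`.
#' @export
split_patchset <- function(ps, val_fraction = 0.1, seed = NULL) {
  stopifnot(inherits(ps, "patch_set"), val_fraction >= 0, val_fraction < 1)
  n <- length(ps)
  n_val <- max(if (val_fraction > 0) 1L else 0L, round(val_fraction * n))
  ps$val_idx <- with_seed(seed, sort(sample.int(n, n_val)))
  ps
}

#' Serialize / load a patch set
#'
#' The container is a pair of files: `<path>.rds` holding the arrays and
#' `<path>.json` a human-readable manifest (counts, shapes, threshold).
#' Round trips preserve patches bitwise.
#'
#' @param ps A `patch_set`.
#' @param path Base path (without extension).
#' @return The path / the restored `patch_set`.
#' @export
write_patchset <- function(ps, path) {
  stopifnot(inherits(ps, "patch_set"))
  saveRDS(ps, paste0(path, ".rds"))
  manifest <- list(n_patches = length(ps),
                   patch_shape = ps$patch_shape,
                   threshold = ps$threshold,
                   norms_range = range(ps$norms))
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_patchset
#' @export
read_patchset <- function(path) {
  ps <- readRDS(paste0(path, ".rds"))
  stopifnot(inherits(ps, "patch_set"))
  ps
}
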