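# Shared I/O and the end-to-end pipeline.
#
# Image stacks are single- or multi-page grayscale TIFFs with a JSON
# sidecar (`<stem>.json`) carrying acquisition metadata (pixel size in nm,
# dwell time in us) and the intensity scale.  TIFF float storage is
# holds values in [0, 1] at 32-bit depth, so stacks are written divided by
# a power-of-two scale recorded in the sidecar (integer count data is
# flagged and rounds back exactly on read; general floats round-trip to
# within 2^-32 of the scale).
# Coordinate convention, used everywhere in the package: arrays are
# indexed (y, x) for frames and (y, x, frame) or (y, x, z) for stacks,
# 1-based.

sidecar_path <- function(path) paste0(sub("\\.tiff?$", "", path), ".json")

#' Read an image stack from TIFF
#'
#' Pages are returned in stored order as an array `(y, x, frame)` (a
#' single page gives a matrix).  Pixel size and dwell time are read from
#' the JSON sidecar when present; otherwise the stack loads with
#' `metadata_known = FALSE` and no failure.
#'
#' @param path TIFF file path.
#' @return Numeric array with attributes `pixel_size`, `dwell_time`
#'   (possibly `NA`) and `metadata_known`.
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(dim(pages[[1]])) == 3L) {
    stop("RGB TIFF is not supported: expected single-channel grayscale ",
         "(got ", dim(pages[[1]])[3], " samples per pixel)", call. = FALSE)
  }
  out <- if (length(pages) == 1L) pages[[1]] else
    array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    out <- out * (meta$scale %||% 1) + (meta$offset %||% 0)
    if (isTRUE(meta$integral)) out <- round(out)
    attr(out, "pixel_size") <- meta$pixel_size %||% NA_real_
    attr(out, "dwell_time") <- meta$dwell_time %||% NA_real_
    attr(out, "metadata_known") <- TRUE
  } else {
    attr(out, "pixel_size") <- NA_real_
    attr(out, "dwell_time") <- NA_real_
    attr(out, "metadata_known") <- FALSE
  }
  out
}

#' Write an image stack to TIFF with a JSON sidecar
#'
#' Data are stored as 32-bit grayscale pages divided by the smallest power
#' of two not below the data maximum (TIFF pages hold values in `[0, 1]`);
#' the scale and any metadata go to the sidecar.  Integer photon counts
#' are flagged as such and restored exactly on read.
#'
#' @param x Matrix or `(y, x, frame)` array.
#' @param path Output TIFF path.
#' @param pixel_size,dwell_time Metadata stored in the sidecar (defaults:
#'   the array's attributes).
#' @param extra Named list of additional sidecar fields.
#' @return `path`, invisibly.
#' @export
write_stack <- function(x, path, pixel_size = attr(x, "pixel_size"),
                        dwell_time = attr(x, "dwell_time"), extra = list()) {
  offset <- min(x, 0)                      # restored images may dip below 0
  scale <- 2^ceiling(log2(max(x - offset, 1)))
  d <- dim(x)
  pages <- if (length(d) == 3L) {
    lapply(seq_len(d[3]), function(t) (x[, , t] - offset) / scale)
  } else {
    list((as.matrix(x) - offset) / scale)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- c(list(scale = scale, offset = offset,
                 integral = all(x == round(x)),
                 pixel_size = pixel_size %||% NA_real_,
                 dwell_time = dwell_time %||% NA_real_),
            extra)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' Pipeline configuration
#'
#' Stage parameters for the end-to-end demo pipeline (simulate, register,
#' patch, train, predict, evaluate).  Defaults are the full-scale study
#' settings; the `demo` profile shrinks every stage so the pipeline runs
#' on a laptop CPU in minutes.
#'
#' @param seed Master seed; every stochastic stage derives from it.
#' @param dims 2 or 3.
#' @param shape Simulated frame shape.
#' @param n_pairs Number of simulated training pairs.
#' @param kind Phantom kind.
#' @param dwell_fast,dwell_slow Pixel dwell times (us).
#' @param patch_shape,n_patches,threshold Patch preparation settings.
#' @param network A [network_config()].
#' @param training A [train_config()].
#' @param loss A [loss_config()].
#' @return An object of class `run_config`.
#' @export
pipeline_config <- function(seed = 1L, dims = 2L,
                            shape = c(2048L, 2048L), n_pairs = 20L,
                            kind = "filaments",
                            dwell_fast = 0.072, dwell_slow = 2.3,
                            patch_shape = c(256L, 256L),
                            n_patches = 1200L, threshold = 0.3,
                            network = network_config(dims = dims),
                            training = train_config(),
                            loss = loss_config()) {
  structure(list(seed = as.integer(seed), dims = as.integer(dims),
                 shape = as.integer(shape), n_pairs = as.integer(n_pairs),
                 kind = kind, dwell_fast = dwell_fast,
                 dwell_slow = dwell_slow,
                 patch_shape = as.integer(patch_shape),
                 n_patches = as.integer(n_patches), threshold = threshold,
                 network = network, training = training, loss = loss),
            class = "run_config")
}

#' Demo-scale pipeline configuration
#'
#' A small profile (64 x 64 patches, tiny network, few epochs) exercising
#' every stage end to end in a few minutes on one CPU.
#'
#' @param seed Master seed.
#' @return A `run_config`.
#' @export
demo_config <- function(seed = 1L) {
  pipeline_config(
    seed = seed,
    shape = c(192L, 192L), n_pairs = 3L,
    patch_shape = c(64L, 64L), n_patches = 40L,
    network = network_config(unet_base_filters = 8L, n_residual_groups = 1L,
                             n_cab_per_group = 2L),
    training = train_config(epochs = 6L, initial_lr = 1e-3, seed = seed))
}

config_hash <- function(config) {
  declass <- function(x) if (is.list(x)) lapply(unclass(x), declass) else x
  s <- as.character(jsonlite::toJSON(declass(config), auto_unbox = TRUE,
                                     digits = NA))
  sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 97 + 1))
}

#' Run the full restoration pipeline on simulated data
#'
#' Simulate training pairs, register them, build and filter the patch
#' set, train the UNet-RCAN, restore a held-out simulated test frame and
#' report metrics.  Artifacts (TIFFs, checkpoint, history CSV, metrics
#' JSON and a manifest) are written under `out_dir`.
#'
#' @param config A [pipeline_config()] / [demo_config()].
#' @param out_dir Output directory.
#' @param verbose Print stage progress.
#' @return A list with the trained model, the metrics report and the
#'   manifest (also written to `manifest.json`).
#' @export
run_pipeline <- function(config = demo_config(), out_dir = tempfile("run"),
                         verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t_start <- proc.time()[3]
  say <- function(...) if (verbose) message(sprintf(...))
  seeds <- child_seeds(config$seed, config$n_pairs + 3L)
  optics <- optics_model()

  say("stage simulate: %d pairs of %s", config$n_pairs,
      paste(config$shape, collapse = "x"))
  pairs <- lapply(seq_len(config$n_pairs), function(i) {
    ph <- phantom(config$kind, shape = config$shape, seed = seeds[[i]])
    simulate_pair(ph, optics, config$dwell_fast, config$dwell_slow,
                  seed = seeds[[i]])
  })

  say("stage register")
  regs <- lapply(pairs, function(p) {
    r <- register_pair(p$noisy, p$gt)
    p$noisy <- r$noisy
    p
  })

  say("stage dataset: %d patches of %s, threshold %.2f", config$n_patches,
      paste(config$patch_shape, collapse = "x"), config$threshold)
  per_pair <- ceiling(config$n_patches / config$n_pairs)
  raw <- combine_patches(lapply(seq_along(regs), function(i)
    extract_patches(regs[[i]], config$patch_shape, max_patches = per_pair,
                    seed = seeds[[i]])))
  ps <- filter_patches(raw, config$threshold)
  ps <- split_patchset(ps, config$training$val_fraction, config$seed)

  say("stage train: %d epochs on %d patches", config$training$epochs,
      length(ps))
  model <- build_unet_rcan(config$network, seed = config$seed)
  model <- train_model(model, ps, config$training, config$loss,
                       verbose = verbose)
  save_checkpoint(model, file.path(out_dir, "checkpoint"))
  utils::write.csv(model$history, file.path(out_dir, "history.csv"),
                   row.names = FALSE)

  say("stage predict + evaluate")
  test_seed <- seeds[[config$n_pairs + 1L]]
  test_ph <- phantom(config$kind, shape = config$shape, seed = test_seed)
  test_pair <- simulate_pair(test_ph, optics, config$dwell_fast,
                             config$dwell_slow, seed = test_seed)
  noisy_n <- normalize_patch(test_pair$noisy)
  pred <- predict(model, strip_attrs(noisy_n),
                  tile = min(config$patch_shape[1], dim(noisy_n)[1]))
  truth_n <- strip_attrs(normalize_patch(test_pair$truth))
  scales <- max(1L, min(5L, floor(log2(min(dim(pred)) / 11)) + 1L))
  report <- metrics_report(list(truth_n, truth_n),
                           list(pred, strip_attrs(noisy_n)), scales = scales)
  report$per_image$image <- c("restored", "noisy_input")
  write_stack(pred, file.path(out_dir, "restored.tif"),
              pixel_size = test_pair$pixel_size)
  write_stack(test_pair$noisy, file.path(out_dir, "noisy.tif"),
              pixel_size = test_pair$pixel_size,
              dwell_time = config$dwell_fast)

  manifest <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("stedrestore")),
    n_pairs = config$n_pairs,
    n_patches_kept = length(ps),
    epochs = config$training$epochs,
    best_val_loss = min(model$history$val_loss),
    metrics = list(
      psnr_restored = report$per_image$psnr[1],
      psnr_noisy = report$per_image$psnr[2],
      ms_ssim_restored = report$per_image$ms_ssim[1],
      nmse_restored = report$per_image$nmse[1]),
    wall_time_s = unname(proc.time()[3] - t_start))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done in %.1f s", manifest$wall_time_s)
  invisible(list(model = model, report = report, manifest = manifest,
                 out_dir = out_dir))
}
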