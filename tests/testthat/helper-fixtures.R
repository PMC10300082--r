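# Shared fixtures, all generated in code.

std_optics <- function(power = 0.75) {
  optics_model(confocal_fwhm = 240, sted_power_fraction = power,
               saturation_power_fraction = 0.05)
}

# A small filament pair at the study dwell times (0.072 / 2.3 us).
small_pair <- function(seed = 1L, shape = c(128L, 128L)) {
  ph <- phantom("filaments", shape = shape, seed = seed)
  simulate_pair(ph, std_optics(), seed = seed)
}

# Noiseless blurred filament image (registration / blur fixtures).
noiseless_image <- function(seed = 2L, shape = c(64L, 64L), n = 4L) {
  ph <- phantom("filaments", shape = shape, seed = seed, n_structures = n)
  psf_blur(render_phantom(ph), std_optics(), 20)
}

# Bright bead image, the fixture for resolution estimators (bead
# calibration acquisitions are long-dwell and bright).
bead_image <- function(power = 0.75, seed = 8L, dwell = 90,
                       brightness = 200, shape = c(512L, 512L)) {
  ph <- phantom("puncta", shape = shape, seed = 4L, n_structures = 300L)
  truth <- psf_blur(render_phantom(ph), std_optics(power), 20)
  acquire(truth, acquisition_model(dwell, brightness = brightness,
                                   background = 0.5), seed = seed)
}

# Patch set for training smoke tests: 40 filament patches of 64 x 64,
# 32 train / 8 held out.
smoke_patchset <- function() {
  pairs <- lapply(1:8, function(i) {
    ph <- phantom("filaments", shape = c(192L, 192L), seed = 100L + i)
    simulate_pair(ph, std_optics(), seed = 200L + i)
  })
  raw <- combine_patches(lapply(seq_along(pairs), function(i)
    extract_patches(pairs[[i]], c(64L, 64L), max_patches = 24L,
                    seed = 300L + i)))
  ps <- filter_patches(raw, 0.3)
  stopifnot(length(ps) >= 40L)
  keep <- seq_len(40L)
  for (nm in c("noisy", "gt", "truth")) ps[[nm]] <- ps[[nm]][keep]
  ps$norms <- ps$norms[keep]
  ps$provenance <- ps$provenance[keep, ]
  ps$val_idx <- 33:40
  ps
}

tiny_config <- function(dims = 2L) {
  network_config(dims = dims, unet_base_filters = 8L,
                 n_residual_groups = 1L, n_cab_per_group = 2L)
}

strip <- function(x) {
  d <- dim(x)
  attributes(x) <- NULL
  dim(x) <- d
  x
}
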