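# stedrestore

Fast, gentle STED microscopy by image restoration. STED (stimulated
emission depletion) microscopy resolves subcellular structure below 60 nm,
but the depletion beam bleaches fluorophores and stresses live cells.
Shortening the pixel dwell time Δt cuts the light dose proportionally —
and with it the photon count, since expected counts are linear in Δt — so
fast STED frames are buried in Poisson shot noise. `stedrestore` trains a
two-step deep network to map short-dwell, low-SNR STED images onto their
long-dwell, high-SNR counterparts, letting dwell times drop by one to two
orders of magnitude: image fast, restore, and keep imaging where
conventional STED would have bleached the sample within a handful of
frames.

The package is aimed at microscopists and image-analysis developers who
want the full computation in one place, testable end to end without any
microscope data: a synthetic STED simulator stands in for the instrument.

## What is inside

* **Model** — two-step UNet-RCAN: a residual U-Net (3 poolings, 64 base
  filters, channel-attention skip connections) followed by a residual
  channel attention network (3 residual groups × 8 channel attention
  blocks, 64 filters) that consumes the U-Net output concatenated with
  the raw noisy input. 2D and 3D variants; forward and backward passes
  implemented natively in R (im2col + BLAS), gradient-checked.
* **Training** — Charbonnier + edge (Laplacian) loss
  `L = L_char + 0.05 * L_edge` with ε = 1e-3, Adam at batch size 1,
  cosine-annealed learning rate from 1e-4.
* **Simulator** — filament / puncta / hollow-tube phantoms, effective
  Gaussian PSF following the STED scaling law
  `d = d_conf / sqrt(1 + P/Psat)`, per-pixel Poisson acquisition with
  dwell-linear expectation, exponential photobleaching time-lapses.
* **Noise calibration** — semi-synthetic training data: scale a high-SNR
  image by λ, Poisson-sample it, and fit λ by histogram MSE against a
  real fast acquisition (5-repeat average).
* **Registration** — Fourier-domain cross-correlation drift correction
  with invalid-margin masking.
* **Dataset** — aligned patch extraction, per-patch max normalization,
  L2-norm content filtering (threshold 0.2–0.4).
* **Evaluation** — PSNR, NMSE, MS-SSIM, Gaussian line-profile FWHM,
  decorrelation-analysis resolution, photobleaching curves.

## Worked example

Simulate a microtubule-like field at the study dwell times (72 ns noisy /
2.3 µs ground truth), train a scaled-down model, and restore a held-out
frame:

```r
library(stedrestore)

ph    <- phantom("filaments", shape = c(192, 192), seed = 1)
pair  <- simulate_pair(ph, optics_model(), dwell_fast = 0.072,
                       dwell_slow = 2.3, seed = 1)
pair
#> <training_pair> 192x192 px, dwell 0.072 / 2.3 us (mean counts 0.0749 / 2.31)

mean(pair$gt) / mean(pair$noisy)     # ~30-fold exposure contrast
#> [1] 30.78168

# patch preparation: max-normalize, filter low-content patches
raw <- extract_patches(pair, c(64, 64), max_patches = 16, seed = 1)
ps  <- filter_patches(raw, threshold = 0.3)
ps
#> <patch_set> 10 pairs of 64x64 patches (threshold 0.30)

# a miniature network trains in minutes on one CPU
cfg   <- network_config(unet_base_filters = 8, n_residual_groups = 1,
                        n_cab_per_group = 2)
model <- build_unet_rcan(cfg, seed = 7)
model <- train_model(model, split_patchset(ps, 0.25, seed = 7),
                     train_config(epochs = 10, initial_lr = 3e-3, seed = 7))

truth <- normalize_patch(pair$truth)           # noiseless oracle
noisy <- normalize_patch(pair$noisy)
pred  <- predict(model, noisy)
psnr(truth, pred) - psnr(truth, noisy)         # restoration gain, dB
#> [1] 4.152842
```

The restoration gain says the network recovered ~4 dB of fidelity over
the raw 72-ns acquisition relative to the noiseless reference — the
miniature version of the denoising the method delivers at full scale.
Resolution is assessed with the two estimators the package provides:

```r
img <- psf_blur(render_phantom(phantom("puncta", shape = c(512, 512),
                                       n_structures = 300, seed = 4)),
                optics_model(240, 0.75, 0.05), 20)   # 60 nm effective PSF
beads <- acquire(img, acquisition_model(90, brightness = 200), seed = 8)
decorrelation_resolution(beads, pixel_size = 20)$resolution_nm
#> [1] 65.33333
```

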