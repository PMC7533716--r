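# leukosr

Geometry-prior single-image super-resolution (SISR) for stained leukocyte
micrographs, with a fully seeded synthetic leukocyte generator, MATLAB-
compatible bicubic degradation, and a PSNR/SSIM evaluation harness.

## The problem

White blood cells are classified largely by nuclear shape: how many lobes a
neutrophil nucleus has, whether lobes adhere, how a lymphocyte's single
nucleus fills the cell. A super-resolver that smooths or hallucinates this
structure is worse than useless for haematology, because the structure *is*
the diagnostic signal. `leukosr` implements a two-network model that makes
reconstruction respect cell geometry:

- a **prior network** `I_M = f1(I_LR; θ1)` — a half-width U-net that
  predicts a 3-channel *parsing map* (per-pixel probabilities of nucleus,
  cytoplasm, background) from the bicubically pre-upsampled low-resolution
  luminance `I_LR`;
- an **SR network** `I_SR = f2(I_LR, I_M; θ2)` — a residual network without
  batch normalisation (shallow feature extractor, 3-residual-block encoder,
  a mask encoder of the same depth on `I_M`, a 192-channel fusion, and a
  3-residual-block decoder ending in a 1×1 convolution).

The two are trained **jointly, end to end**, with the loss

```
L = mean_i [ ρ(I_SR_i − Î_SR_i) + λ · BCE(I_M_i, Î_M_i) ],   ρ(x) = √(x² + ε²)
```

with Charbonnier constant `ε = 1e-3` and `λ = 1` (Adam, minibatch 8). Only
luminance is super-resolved; chroma is bicubically upscaled and reattached.
Dropping the prior branch and mask encoder yields the **none-prior**
ablation (128-channel fusion), which isolates what the geometry prior buys.

Because the cell-imaging dataset this model family was developed on is
private, the package ships a deterministic synthetic generator —
Fourier-perturbed elliptical cytoplasm, multi-lobed nuclei as clipped blob
unions, Wright–Giemsa-like palette, band-limited texture, Gaussian blur —
that emits exact parsing-map ground truth and stands in for the dataset in
all training and evaluation.

## Worked example

Generate a small synthetic dataset and fit the geometry-prior model at 4×
(a few minutes on one CPU):

```r
library(leukosr)

ds <- generate_dataset(60, split = c(50/60, 4/60, 6/60), seed = 5,
                       image_size = 32, blur_sigma = 0.5)
print(ds)
#> Synthetic leukocyte dataset: 60 samples (train=50, val=4, test=6)
#> Classes: basophil=12, eosinophil=12, lymphocyte=12, monocyte=12, neutrophil=12

fit <- leukosr_fit(ds, scale = 4, variant = "geometry-prior",
                   train = train_config(batch_size = 8, learning_rate = 1e-3,
                                        epochs = 40, seed = 5),
                   prior = prior_net_config(base_width = 16, depth = 4),
                   sr = sr_net_config(feature_width = 32))
print(fit)
#> Fitted leukocyte SR model (geometry-prior, scale 4x)
#>   epochs: 40, best epoch by validation PSNR: 39 (27.052 dB)
#>   final train loss: 0.12932 (sr 0.02959, prior 0.09974)

evaluate_segmentation(fit, split_samples(ds, "test"), scale = 4)$accuracy
#> [1] 0.9316406
```

The parsing-map prior is already accurate (93% of pixels correctly
classified on held-out cells), but 50 training images are not enough for
the SR branch to beat plain bicubic upscaling — reconstruction needs the
study-scale run below. `predict()` on a fitted model runs the full
inference path (degrade → predict map → super-resolve luminance → reattach
bicubic chroma):

```r
sr_rgb <- predict(fit, split_samples(ds, "test")[[1]], type = "rgb")
```

At the package's study scale (200 training images, same 40-epoch protocol),
training both variants and benchmarking them against bicubic —
`run_ablation(seed = 1)`, about 13 minutes on one CPU — prints:

```
Ablation study: 200 train / 30 test synthetic cells, 32 px, scale 4x, 40 epochs
Luminance PSNR/SSIM by scale and variant
  scale 4x:
    geometry-prior   PSNR  29.5275 dB   SSIM 0.8793   (n = 30)
    none-prior       PSNR  28.7600 dB   SSIM 0.8443   (n = 30)
    bicubic          PSNR  27.9947 dB   SSIM 0.8075   (n = 30)
  prior segmentation accuracy at x4: 0.9616
  prior segmentation accuracy at x8: 0.8508
```

Reading the numbers: the `bicubic` row is the degraded input itself, so the
gaps are what learning adds on the luminance channel — here +0.77 dB for
conditioning the same SR network on the predicted parsing map, the
direction (and rough magnitude) of the improvement this model family
reports at full scale. Segmentation accuracy is the fraction of pixels
whose argmax class matches the exact generated mask; the 8× figure is the
4×-trained prior evaluated under twice-harsher degradation, where a 32-px
cell retains only a 4×4-pixel true observation.

A thin CLI over the same functions lives at `inst/cli/leukosr.R`
(`generate`, `degrade`, `train`, `evaluate`, `ablate`).

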