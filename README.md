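# mpfnet

Label-free prediction of organelle fluorescence from hyperspectral
stimulated Raman scattering (SRS) microscopy stacks, in R.

SRS microscopy images living cells without dyes: each channel records the
signal at one vibrational transition, approximately linear in the local
concentration of the resonant chemical bonds. Because organelles share
overlapping molecular composition, the channels are spectrally mixed — no
single channel shows one organelle. This package trains an image-to-image
network that maps a C-channel SRS stack to the three fluorescence channels
a dye panel would have produced (nucleus, mitochondria, endoplasmic
reticulum), for microscopists and computational biologists who want
in-silico labeling without hand-mixing models.

## What is inside

* **The fusion network.** Two parallel encoders — a four-stage residual
  CNN (local detail; feature pyramid at H/4, H/8, H/16) and an 8-layer
  patch-embedding transformer (global context; pre-norm layers
  `a = z + MSA(LN(z))`, `z' = a + MLP(LN(a))`, decoder maps at the same
  three scales) — fused level-by-level. Each level combines
  squeeze-excitation channel attention `s_hat = sigmoid(W2 relu(W1 z)) ⊙ s`,
  pyramid-kernel (1×1/3×3/5×5) spatial attention on channel-wise
  mean/max maps, and a bilinear term `Conv((s W1) ⊙ (h W2))`, merged by a
  residual concat-convolution. Levels cascade coarse-to-fine through
  attention-gated skips `s_hat = s · sigmoid(psi' relu(Wx's + Wg'g + b))`.
  A plain U-net baseline with the same contract is included.
* **A reverse-mode autodiff engine** in pure R (tape-based; conv via
  im2col, attention, normalization layers, pooling, gradient-checked
  against finite differences), so the networks are trainable on CPU with
  no external deep-learning runtime.
* **The evaluation suite**: NRMSE, PSNR, SSIM, Pearson correlation, Dice,
  mean IoU, per-class accuracy; per-organelle report tables
  (means ± sd) and pairwise relative-change comparisons
  (`100(a−b)/b` for quality metrics, `100(b−a)/b` for error metrics).
* **A synthetic paired-data generator**: organelle scenes (ellipse
  nuclei, mitochondrial puncta, random-walk reticulum) linearly mixed
  into C noisy channels through overlapping spectral signatures —
  fully seeded and reproducible, so training and evaluation need no
  external data.

## Worked example

```r
library(mpfnet)

cfg <- scene_config(image_size = 32, n_cells = 1)
ds  <- make_dataset_memory(cfg, n_images = 8, split = 0.75, seed = 1)

model <- build_mpfnet(mpfnet_config(in_channels = 10, image_size = 32,
                                    preset = "small", dropout = 0, seed = 1))
fit <- train(model, ds$train,
             train_config(batch_size = 2, epochs = 15, optimizer = "adam",
                          seed = 1))
tail(fit$log[, c("epoch", "loss", "pixel_acc", "pcc")], 3)
#>    epoch       loss pixel_acc       pcc
#> 13    13 0.02749458 0.8172201 0.7214552
#> 14    14 0.02614340 0.8172201 0.7377449
#> 15    15 0.02590690 0.8172201 0.7410440

report <- evaluate_model(model, ds$test, model_name = "mpfnet")
print(as.data.frame(report)[, 1:7], digits = 3)
#>    model    organelle nrmse  ssim   pcc  dice  miou
#> 1 mpfnet      nucleus 0.130 0.365 0.501 0.317 0.545
#> 2 mpfnet mitochondria 0.165 0.497 0.789 0.670 0.711
#> 3 mpfnet           er 0.212 0.420 0.768 0.651 0.692
```

After 15 epochs on six tiny images the loss has dropped an order of
magnitude and the held-out Pearson correlation per organelle reaches
0.5–0.8: the network is learning the unmixing plus morphology, not
memorizing constants. (Longer budgets push training PCC above 0.85; see
the acceptance script.) The report columns mirror the standard
comparison-table layout; `compare_reports()` turns two or more such
tables into relative-change percentages.

A command-line wrapper with `generate`, `train`, `predict`, `evaluate`
and `compare` subcommands lives at `inst/cli/mpfnet.R`; the methods
vignette (`vignettes/mpfnet-methods.Rmd`) documents the model,
parameters, numerical choices and limitations.

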