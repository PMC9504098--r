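---
title: "Predicting organelle fluorescence from hyperspectral SRS stacks: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting organelle fluorescence from hyperspectral SRS stacks: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpfnet)
```

## The problem

Stimulated Raman scattering (SRS) microscopy images living cells without
fluorescent labels: each image channel records the signal at one
vibrational transition, roughly proportional to the local concentration of
the chemical bonds resonant at that wavenumber. Because every organelle
contains overlapping mixtures of proteins, lipids and nucleic acids, the
per-channel images are *spectrally mixed* — no single vibrational channel
shows one organelle cleanly. In-silico labeling asks a model to invert
this mixing and the morphology prior jointly: given a C-channel
hyperspectral stack, predict the fluorescence images that nucleus-,
mitochondria- and endoplasmic-reticulum-specific dyes (e.g. Hoechst 33342,
MitoTracker Red, ER-Tracker Green) would have produced.

This package implements a two-branch fusion network for that task, a
plain U-net style baseline, the image-quality metric suite used to score
such predictions, and a synthetic paired-data generator, all in R on a
purpose-built reverse-mode automatic differentiation engine (no external
deep-learning runtime).

## Architecture

The network has four parts.

**CNN branch.** A stride-2 convolutional stem is followed by four stages
of residual blocks (two 3×3 convolutions with instance normalization and
ReLU inside the main path, identity or 1×1-projection shortcut). Stage 1
widens channels at constant resolution; stages 2–4 each halve the
resolution. The pyramid levels exported to the fusion module are the
outputs of stages 2, 3 and 4, at 1/4, 1/8 and 1/16 of the input
resolution, written `h2`, `h1`, `h0`. Downsampling uses stride-2
convolutions rather than pooling so the reduction is learnable.

**Transformer branch.** The input stack is cut into 16×16 patches, each
flattened and embedded bias-free into `S0` dimensions, plus a learnable
positional table — `z0 = x0 + pos`. Eight pre-norm transformer layers
follow: `a = z + MSA(LN(z)); z' = a + MLP(LN(a))`, with multi-head scaled
dot-product attention (`softmax(q k'/sqrt(d)) v`, head dimension
`d = S0/heads`) and a linear–GELU–dropout–linear MLP. The decoder
reshapes the final tokens onto the H/16 grid and recovers H/8 and H/4
maps by nearest-upsample + 3×3 convolution + instance norm (`s0`, `s1`,
`s2`), mirroring the CNN pyramid scales.

**Parallel fusion.** At each level *i* the two branches are combined by
three mechanisms and a residual merge:

* *channel attention* (squeeze-excitation) on the transformer map:
  global-average-pooled descriptor, bottleneck MLP (reduction ratio 4),
  sigmoid scales in (0, 1) multiplying each channel;
* *spatial attention* on the CNN map: channel-wise mean and max maps,
  concatenated and convolved with a 1×1/3×3/5×5 kernel pyramid; the
  per-kernel sigmoids are summed, so the attention map lies in (0, 3)
  (an optional flag normalizes by 3);
* a *bilinear Hadamard* term `Conv3x3((s W1) ⊙ (h W2))` coupling the two
  branches through channel-wise projections to a common width;
* a *residual fuse*: the three results are concatenated (bilinear,
  channel-attended, spatial-attended — the order is part of the
  contract), passed through a 3×3 convolution plus a 1×1 projection
  shortcut, and instance-normalized.

The fused levels are cascaded coarse-to-fine: the upsampled coarse fusion
is both concatenated with and used as the *gating signal* for an
attention gate on the finer fusion
(`alpha = sigmoid(psi' relu(Wx's + Wg'g + b))`, `s_hat = s * alpha`),
followed by a 3×3 convolution and instance norm. The cascade ends at the
H/4 map.

**Prediction head.** Two rounds of nearest-upsample + 3×3 convolution +
ReLU restore the full resolution, then a 1×1 convolution and a sigmoid
emit the K = 3 organelle channels in [0, 1]. The final 1×1 layer is
zero-initialized so a freshly built network predicts 0.5 everywhere —
gradients then flow immediately instead of fighting a saturated sigmoid.

### Numerical choices that matter

* **Normalization.** All normalization is per-sample (instance norm for
  feature maps, layer norm for tokens), so training and inference behave
  identically at any batch size. The instance norms added after the
  residual fuse and the cascade convolutions are load-bearing: the
  bilinear term grows quadratically in the branch activations, and
  without renormalization the fused features reach scales of order 10^3,
  saturating the output sigmoid irrecoverably.
* **Transformer layer form.** The layer is the standard pre-norm block
  with *both* residual connections. A formulation that drops the first
  identity path would make each layer's output independent of its
  input's identity component and could not be the identity map at
  initialization — a property the test suite checks (with zeroed MSA
  output projections and zeroed second MLP layers the 8-layer encoder is
  exactly the identity on tokens).
* **Spatial-attention kernels.** The pyramid follows the (2k−1) rule,
  k = 1..3, i.e. 1×1, 3×3, 5×5 — three receptive-field scales rather
  than three identical 3×3 kernels.
* **Bilinear operand.** The two projections act on the *two different
  branches* (`s W1` with `W1` on the transformer width, `h W2` on the
  CNN width); projecting the same map twice would type-check only for
  one branch and defeat the cross-branch coupling the term exists for.
* **Gradient clipping.** The training loop clips the global gradient
  norm (default 1). Early in training a single oversized step can push
  every ReLU in the head into the dead region at once; clipping removes
  that failure mode without changing converged behaviour.
* **Optimizers.** SGD with momentum 0.9 and weight decay 1e-4 is the
  default, matching the published training protocol (momentum 0.9,
  batch size 8, weight decay 1e-4, initial learning rate 0.001, at most
  200 epochs). An Adam option exists for small-sample experiments, where
  SGD's single global step size converges impractically slowly; the
  package's own end-to-end demonstrations use it.

## Evaluation metrics

Predictions are scored per organelle channel:

* **NRMSE** — RMSE divided by the dynamic range (max − min) of the
  reference image. The formulation leaves the normalizer ambiguous
  between the prediction's and the reference's range; we use the
  reference, the convention of standard implementations (for predictions
  close to the truth the two agree).
* **PSNR** — `10 log10(v_max^2 / MSE)`; infinite for identical images.
* **SSIM** — mean over local Gaussian-weighted 11×11 windows (sigma 1.5,
  valid-mode) of luminance × contrast × structure with exponents 1 and
  stabilizers C1 = (0.01 L)², C2 = (0.03 L)², C3 = C2/2; these are the
  standard constants of the index, which the source formulation leaves
  unspecified.
* **PCC** — Pearson correlation over flattened pixels. On binary inputs
  this coincides with the Matthews correlation coefficient; the package
  computes it on the continuous intensities.
* **Dice and mIoU** — segmentation overlap measures, applied to
  continuous predictions after min-max normalization and thresholding at
  0.5 (`binarize()`; Otsu's method is available as an alternative
  policy). A class absent from both maps has undefined IoU and is
  excluded from the mean rather than scored 0; two empty masks have
  Dice 1 (vacuous agreement). For binary masks Dice = 2·IoU/(1 + IoU)
  exactly, which the tests assert on random masks.

`build_report()` aggregates means ± standard deviations over a test set
into the standard comparison-table layout, and `compare_reports()`
produces pairwise relative changes: for error metrics the *reduction*
`100(b − a)/b`, for quality metrics the *improvement* `100(a − b)/b`,
rounded to two decimals. `reference_metric_tables()` ships the reported
per-organelle means of the three benchmark predictors so those published
comparison percentages can be recomputed; the underlying images are
available only on request from the original authors, so the absolute
table values are not recomputable here.

## Synthetic data generator

Real paired SRS/fluorescence data is not publicly deposited, so the
package generates its own. The forward model is deliberately simple and
physics-first: SRS signal is approximately linear in molecular
concentration, so each input channel is a *nonnegative linear mixture*
of the organelle maps through a C×3 spectral signature matrix, plus a
nonspecific background, Poisson shot noise (gain 50 photons per
intensity unit) and Gaussian read noise (sd 0.02), clipped at zero. The
default signatures are Gaussian profiles on the channel axis (centres at
30 %, 55 % and 80 % of the sweep, width 25 % of the sweep, floor 0.05),
wide enough that neighbouring signatures overlap substantially — the
spectral-overlap regime that makes the task nontrivial.

Scenes contain ellipse nuclei, punctate mitochondria scattered in a
cytoplasmic annulus and excluded from nuclei, and an endoplasmic
reticulum drawn as persistent random walks seeded at the nuclear
envelope — a qualitative match to reticular morphology, chosen for
fixture realism rather than biophysical accuracy. Masks record pre-blur
supports; channels are blurred (Gaussian, sigma 1 px) and normalized to
[0, 1]. Everything is a pure function of (config, seed): datasets are
bit-reproducible, and the default 80/20 train/test split is a seeded
shuffle recorded in a manifest.

Two properties tie the generator to the learning problem and are
asserted in the tests: (i) with the default mixing no input channel
correlates above 0.99 with any single truth channel (the overlap is
real), and (ii) at zero noise a per-pixel linear regression from the
input channels recovers the truth with PCC > 0.8 (the task is solvable,
so a network failing it indicates a model bug, not an impossible
fixture).

What the generator does *not* emulate: physically accurate Raman
spectra, intensity-dependent microscope artifacts, cell-to-cell
morphological variability beyond random placement and size jitter, or
time series. Passing the end-to-end tests therefore demonstrates that
the architecture, gradients and training loop work — not that the
network reaches any particular accuracy on real SRS data.

## Problem sizes used in the shipped experiments

The package's own demonstrations (test suite and `scripts/acceptance.R`)
are sized for a single CPU:

* *Overfit check*: the small-preset network (stage widths 8–32,
  embedding 32), four 64×64 synthetic pairs, Adam, batch 1, at most 200
  epochs with an early exit once training PCC reaches 0.85. It
  typically crosses 0.8 within ~50 epochs.
* *Generalization check*: 20 synthetic 32×32 images (16 train / 4
  test), 25 epochs, identical budget for the fusion network and the
  U-net baseline. The comparison is directional — the fusion model's
  held-out PCC should match or exceed the baseline's — not a claim
  about absolute accuracy at this scale.

The paper-scale preset (`preset = "paper"`: widths 32–256, embedding
256, 512×512 inputs) is configured and functional but far outside
interactive CPU budgets.

## Known limitations

* Pure-R execution: a forward/backward pass on a 64×64 stack takes
  ~0.3 s; the implementation favours correctness and inspectability
  over speed.
* Instance norm (not batch norm) throughout; models expecting
  batch-statistics behaviour will differ.
* The attention-gate bias pair is folded into one bias on the gating
  projection (the two biases of the canonical formulation are
  algebraically redundant before the ReLU).
* `FeaturePyramid`/decoder alignment fixes the patch size at 16; other
  patch sizes would need a different decoder depth.
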