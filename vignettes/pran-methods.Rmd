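---
title: "Pyramid residual attention networks for lesion segmentation: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pyramid residual attention networks for lesion segmentation: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(praseg)
```

## The model

`praseg` implements a convolutional segmentation architecture for dermoscopic
skin-lesion images built from one repeated unit, the **pyramid residual
attention (PRA) block**, and the three-level network (**PRAN**) assembled from
five such blocks.

A PRA block maps a feature map `x` (an `(H, W, C, N)` array) to an output of
the same spatial size along two branches:

* **Branch (a), the residual unit:** two stages of 3x3 convolution, group
  normalization and a rectifier. Group normalization is used instead of batch
  normalization because training runs at batch size 8, where per-batch
  statistics are unreliable.
* **Branch (b), the compressed pyramid-attention path:** a 2x2 stride-2
  max-pool concentrates semantics; a **convolution pyramid** of parallel
  stride-1 kernels of sizes 1, 3, 5, 7 (same-padded, channel-concatenated in
  kernel order) reads several receptive fields at once; **channel attention**
  reweights the concatenated channels; a 2x2 stride-2 transposed convolution
  restores the input resolution.

The channel attention computes gates

```
Y = sigmoid(k2 %*% (k1 %*% (P_gavg(x) + P_gmax(x)) + b1) + b2),   Out = Y (*) x + x
```

where `P_gavg`/`P_gmax` are global average and max pooling over space and
`(*)` is per-channel broadcast multiplication. Two points are deliberate and
differ from the common squeeze-excitation variants: the two pooled
descriptors are **summed before** the shared two-layer bottleneck (not passed
separately and summed after), and the gated map keeps an additive identity
term. Max pooling supplements average pooling so strong local responses are
not washed out.

The block output is the elementwise **sum** of branch (b) (1x1-projected to
the output width when widths differ), branch (a) (likewise projected) and an
identity shortcut (1x1-projected when the input width differs). The additive
reading follows the residual decomposition `H(x) = G(x) + F(x) + x`: the
shortcut keeps gradients alive, branch (a) learns the local correction, and
branch (b) contributes the multi-scale, attention-screened component.

## The three-level network

PRAN is an encoder-decoder flattened into three resolution levels rather than
a U-shaped cascade of many halvings:

* The **shallow** level runs two chained PRA blocks at the input resolution.
  The first block's attention-weighted branch output feeds an intra-level
  skip (a 3x3 convolution), concatenated into the second block's output; a
  further channel-attention stage reweights the concatenation.
* The reweighted shallow tensor descends through two stride-2 max-pools (a
  4x per-dimension reduction) into the **middle** level, which repeats the
  same two-block pattern; another 4x descent feeds the single-block **deep**
  level, which therefore sees 1/16 of each input dimension (a 256x320 input
  gives 16x20 deep maps).
* On the way up, each lower level's output is upsampled by a 4x transposed
  convolution, concatenated with the upper level's reweighted tensor, and
  fused by the level's 3x3 post-process convolution. A 1x1 convolution and
  sigmoid emit the probability map at full resolution.

Inputs must be divisible by 16; the forward pass refuses anything else
rather than silently cropping, and the per-level input sizes are recorded in
a shape trace (`net_forward(net, x)$trace`).

Which tensor descends and which is upsampled is not fully determined by the
source material; the wiring above (post-attention tensor descends,
post-fusion tensor ascends) is recorded in the serializable network spec
(`write_pran_spec()`), so alternatives can be swapped without code changes.

## The channel plan and the published parameter totals

The pyramid branch widths per position are 8/16 (shallow), 32/64 (middle) and
128 (deep), with attention widths 4x those values; the second-attention
widths that result, 160 and 448, match the published per-position table. The
remaining widths are not all stated in the source material: the attention
bottleneck reduction `r`, the residual widths and the fusion/post-process
widths are free. They were fixed **once**, by calibrating against the three
published totals simultaneously — the standalone PRA module (0.1 M), the
standalone shallow level (1.1 M) and the full PRAN (21.6 M):

* attention reduction `r = 2` everywhere;
* residual widths 96/192 (shallow), 192/320 (middle), 512 (deep);
* standalone PRA ablation configuration: pyramid 32, residual 48, output 64
  (124,465 parameters, against 122.45 k reported for the ablation module);
* fusion upsample widths 384 (deep to middle) and 192 (middle to shallow),
  post-process widths 256.

With this plan the three totals come out at 0.124 M, 1.098 M and 21.631 M —
each rounding to the published figure. `count_trainable_parameters()` counts
every independently trainable scalar (kernels, biases, normalization affine
parameters) and is purely structural.

`width_scale` divides every width; the CPU-scale networks in the tests use
`width_scale = 8` (about 340 k parameters for the tiny PRAN).

## Losses, metrics, and degenerate cases

Training minimizes the soft Dice loss
`1 - (2*sum(P*G) + eps) / (sum(P) + sum(G) + eps)` with `eps = 1e-6` in both
numerator and denominator, so two empty masks give loss 0 rather than an
indeterminate form. Evaluation binarizes at threshold 0.5 (a choice, not a
published value) and reports Dice, IoU, accuracy, specificity and
sensitivity per image, aggregated as mean and population standard deviation
in percent — per-image averaging, not pooled pixels, because the published
dispersion columns imply per-image spread. Empty-denominator metrics return
1 when prediction and truth agree on "nothing there", else 0.

One formula in the source material is printed as
`MIOU = k(G, not-P) / (k(G,P) + k(not-G,P) + k(G, not-P))`, i.e.
`FN/(TP+FP+FN)` — that is not an intersection-over-union and contradicts the
magnitudes reported alongside it (which satisfy `MIOU ~ DC/(2-DC)`, the
standard relation). The suite therefore implements the standard
`IoU = TP/(TP+FP+FN)` and records the discrepancy here; the printed variant
is deliberately not offered.

PR/ROC curves are computed by a direct sweep over every distinct predicted
probability with trapezoidal areas; `pROC` serves as an independent
cross-check in the tests, not as the implementation.

## The synthetic generator

Real dermoscopy brings three difficulties: weak lesion/skin contrast,
irregular variable-size lesions, and occluding hair/artifacts. The generator
reproduces exactly these axes, and nothing more: a skin-toned background with
smooth low-frequency texture; a single lesion shaped as a radially perturbed
ellipse (harmonics 2-5, amplitude `boundary_irregularity`), darker than skin
by exactly `contrast`; `hair_count` dark quadratic Bezier strokes of width
1-2 px and intensity 0.1-0.3 drawn over lesion and skin alike; additive
Gaussian pixel noise. The mask is the exact rasterized lesion region
*before* hair and noise, mirroring the fact that ISIC ground truth outlines
the lesion, not the occlusions. Defaults: area fraction in [0.05, 0.4],
irregularity 0.15, contrast 0.25, 6 hairs, noise 0.02 — values chosen once
to make the task learnable but not trivial (an all-positive constant
predictor stays below Dice 0.6 at the hard setting of contrast 0.05 with
heavy hair).

What the generator does **not** emulate: color variegation inside lesions,
multi-lesion fields, vignetting, rulers and gel bubbles, camera color casts.
Passing the desk-scale learning tests therefore demonstrates that the
architecture and training loop work end to end, not that the network reaches
its published benchmark quality on real dermoscopy; the published ISIC
numbers require the real datasets and GPU-scale training and are out of
scope here.

## Training recipe and numerical choices

Two presets ship. The `"paper"` profile reproduces the published recipe:
Adam, weight decay 1e-6, batch size 8, 300 epochs, learning rate 0.3 stepped
to 1e-4 after 30 and 1e-6 after 270 ("iterations" are read as epochs; a
`unit = "step"` flag gives the per-mini-batch reading). An initial rate of
0.3 under Adam is unusually aggressive; it is kept for fidelity, while the
`"desk"` profile used in all tests runs 30 epochs at a constant 1e-3. No
early stopping in either profile; the checkpoint with the best validation
Dice is retained.

Numerical choices:

* Weight initialization is fan-in scaled Gaussian, gain 2 ahead of rectifiers
  and gain 1 for purely linear layers (pyramid branches, projections,
  transposed convolutions). The gain-1 choice matters: with gain 2
  everywhere, the many additive recombinations multiply activation variance
  level over level and the sigmoid head saturates at initialization. The
  head convolution is initialized near zero (gain 0.01) so training starts
  from probability 0.5 everywhere.
* Group normalization uses 8 groups when the width is divisible by 8,
  otherwise the largest divisor not above 8; epsilon 1e-5; population
  variance.
* Max-pool argmax ties break toward the first element in column-major order;
  forward passes are bit-deterministic for fixed weights.
* All randomness (weights, shuffling, generator, augmentation) is seeded;
  augmentations are a pure function of `(seed, draw)`.
* The augmentation rotation fills the image by reflect-padding before
  rotating and the mask with zeros; crops resample a window of scale
  [0.8, 1] and resize back.

## Ablation variants

`make_ablation_variant()` replaces exactly one sub-component with a plain
3x3 convolution of matching input/output widths: `"PM"` swaps the pyramid
for a single convolution to the full attention width, `"CA"` removes the
gating (no sigmoid remains), `"Res"` collapses the residual unit to one
convolution and drops the identity shortcut. Under this width-matched rule
the parameter arithmetic is fixed by structure: a pyramid always costs more
than a width-matched single 3x3 convolution (84 vs 36 multiplier units), and
a 3x3 convolution at the attention width always costs more than the
bottlenecked gating it replaces (9A^2 vs 2A^2/r). The published ablation
table reports a different ordering (pyramid-replaced largest); no
width-matched replacement can reproduce it, and the corresponding acceptance
check documents this honestly rather than bending the replacement rule.

## Problem sizes used in the test suite

The suite trains the width-scale-8 PRAN on 64 synthetic 64x64 images for 30
epochs (held-out Dice at least 0.9), compares the stacked two-block level
against a single block over 3 seeds on 32x32 images, and checks the
architecture totals on the full-width builds, which are constructed but
never trained. These sizes are the package's chosen desk-scale study
conditions; they keep a complete run in the minutes range on one CPU core.

## Known limitations

* CPU-only; no GPU path, no multi-threaded data loading, no mixed precision.
* The transposed convolutions are restricted to kernel = stride (the only
  configuration the architecture uses), so no overlapping-deconvolution
  checkerboard behavior can be studied.
* The full-width PRAN (21.6 M parameters) is buildable and runs forward, but
  training it at the published 256x320 resolution is far outside desk scale.
* Single lesion per image in the generator; multi-lesion fields and
  photorealistic skin are out of scope.
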