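---
title: "Weighted attention residual U-Net: model, weights, and desk-scale evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted attention residual U-Net: model, weights, and desk-scale evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(waresunet)
```

## The problem

Multi-class segmentation of grayscale medical images often faces a *long-tailed*
class distribution: in the 4-class uterine-MRI setting the package's defaults
emulate, the most frequent class appears in about 8× as many images as the
rarest one (image counts 1603/869/1090/201 over 3206 images) and holds more
than 300× its pixel mass (13.5M vs 39.6k pixels). Two things go wrong at once:
the network allocates little capacity to the rare class, and the conventional
remedy — weighting the loss by inverse *pixel* frequency — produces degenerate
weights, because one extra instance of a large-organ class brings thousands of
correlated pixels while a rare small lesion brings a handful.

## Class rebalancing by image counts

The package therefore weights classes by the number of *images* containing
them, which tracks the number of independent instances a network can learn
from. With `N_i` the image count of class `i` among `C` foreground classes,
the inverse-frequency proportion is `P_i = sum_j N_j / N_i` and the loss-side
weight rescales the proportions to sum to the class count:

`W_i = C / (N_i * sum_j 1/N_j)`  (`mode = "sum_to_C"`, `sum(W) = C`)

A sum-to-one variant `W_i = (1/N_i) / sum_j(1/N_j)` (`mode = "sum_to_one"`)
reproduces the normalized form usually printed next to dataset statistics
tables; the two differ exactly by the factor `C`. Both are strictly decreasing
in the count and invariant under rescaling all counts. Background (label 0) is
not part of the published statistics; it receives a neutral
`background_weight = 1` by default. A class with a zero count is a hard error
rather than an infinite weight: a dataset in which a class never occurs cannot
be rebalanced into learnability, and silently dropping or saturating it would
corrupt the remaining weights.

## Network

The segmentation network is a residual U-Net over a ResNet50-style bottleneck
encoder: a 3×3 stride-2 stem convolution (the published design uses 3×3 here,
not the backbone's 7×7), 2×2 max pooling, then four stages of bottleneck
blocks (3/4/6/3 blocks; stage strides 1/2/2/2; widths `base_width × (1,2,4,8)`
with expansion 4). Total downsampling is ×32, so inputs must have sides
divisible by 32 (the loader raises an explicit resize-or-pad error otherwise).

**Channel attention.** Each block's residual branch ends in a 1×1 convolution
and normalization, followed by a channel gate derived from normalization scale
factors: the branch feature is standardized per channel
(`xhat = (x − mu)/sqrt(sigma² + eps)`, batch statistics during training,
running averages with momentum 0.1 at inference), and the gate is

`gate_c = sigmoid(W_c · alpha_c · xhat + beta_c)`, `W_c = alpha_c / sum(alpha)`.

The printed formula is read literally: the shift `beta` is *not* scaled by the
normalized weight. Because the cited normalization-attention literature scales
the whole normalized output, a `nam_style` switch provides
`sigmoid(W_c (alpha_c xhat + beta_c))` for comparison. Raw `alpha` (no absolute
value) is used in the normalization; negative scales are legal as long as the
sum is nonzero (a zero sum is a hard error). The gate multiplies the residual
branch *before* the shortcut addition — gating the sum would also gate the
shortcut, contradicting the residual design.

**Spatial attention bridge.** Every encoder skip is gated before
concatenation: per-pixel channel mean and channel max are stacked into two
planes, convolved with a single 7×7 kernel (zero padding 3, bias), and passed
through a sigmoid; the map multiplies the skip feature across channels.
Padding 3 keeps the spatial extent, which the concatenation requires.

**Decoder.** Four up-steps (bilinear 2× upsampling followed by a 3×3
convolution by default; a 2×2 stride-2 transposed convolution is available via
`upsample_mode`), each concatenating the bridged skip and applying two
3×3 convolution + normalization + ReLU layers at the skip's width; a final
up-step restores the input resolution and a 1×1 projection emits `C + 1`
score planes. The background class is explicit (plane 0); predicted labels are
the argmax with ties broken toward the lower label, so predictions are
deterministic. Decoder widths mirror the encoder skip widths; the published
figure fixes neither these widths nor the stem stride, so these are package
conventions, not literature facts.

Inputs are intensities scaled to [0,1]; no dataset mean subtraction is
applied. Model construction is seeded (He-normal convolutions, unit
normalization scales, `alpha = 1`, `beta = 0` gates) and bit-reproducible from
`(config, seed)`.

## Loss and training

The loss is class-weighted per-pixel cross-entropy normalized by the summed
pixel weights, `sum_p w_{y_p}(−log softmax(s_p)[y_p]) / sum_p w_{y_p}` — so it
is invariant under rescaling all weights and reduces exactly to plain mean
cross-entropy under uniform weights. Class weights are computed once from the
training-split statistics before training, matching the design in which weight
calculation is a preprocessing step; dynamic per-iteration reweighting is out
of scope. The optimizer is Adam without a schedule. Training, shuffling and
initialization each draw from private seeded RNG streams, so runs are exactly
reproducible; a non-finite loss aborts with a diagnostic rather than training
on. Alongside the final parameters, [train_model()] returns the checkpoint
with the best overall foreground IoU among the epochs at which metrics were
evaluated, which is the model-selection convention the command-line trainer
writes to disk.

The implementation is native R/Rcpp: im2col + BLAS GEMM convolutions and a
small reverse-mode tape over the fixed architecture. Every layer's backward
pass is verified against central finite differences in the test suite, and
both attention gates are additionally verified against scalar-loop oracle
implementations.

## Synthetic long-tailed data

The generator emulates the structural features of the study data that the
method targets, not MRI physics. Each image (default 64×64) includes class `i`
with probability `p_i`; the long-tail preset uses
`p = (0.50, 0.27, 0.34, 0.063)` — the 1603:869:1090:201 image-frequency ratios
— and class-specific elliptical blobs: one large class-1 region (radius 10–16
px), intermediate classes 2–3, and 1–3 tiny class-4 instances (radius 1.2–2.2
px), giving an expected class-1:class-4 pixel ratio well beyond 100:1.
Instances are connected elliptical regions rather than pixel noise because the
rebalancing argument is about *instances*: new images of a class contribute
learnable instances, single pixels do not. Painting proceeds in order of
decreasing expected blob size and never overwrites existing labels, so the
rare class, painted last, is never swallowed; blob centres are drawn from
still-unlabeled pixels so an included class always leaves at least one visible
pixel. Grayscale intensity is class mean ± per-instance contrast jitter plus
pixelwise Gaussian noise (sd 0.05), clipped to [0,1] and quantized to the
8-bit grid so datasets round-trip bit-exactly through PNG. What passing tests
on these data do **not** show: robustness to anatomy-shaped regions, intensity
non-uniformity (bias fields), Rician noise, or inter-patient variability —
on real MRI the intensity classes overlap far more than here.

## Metrics

Evaluation accumulates a single confusion tally over all pixels of a dataset
(micro accumulation; deterministic under image reordering) and reports
per-class IoU, sensitivity and precision in percent. Cells with a zero
denominator are flagged undefined (`NA`) and excluded from means with a
warning — coercing 0/0 to 0 or 100 would silently reward empty predictions.
The "Overall" column is the unweighted (macro) mean over the four foreground
classes, matching the published comparison tables; an `all_class_macro`
convention including background is provided because at least one published
ablation table is only consistent with that reading. Published per-class IoU
rows and their printed Overall cells agree with this convention to half a
unit in the last printed decimal, which the test suite checks on a fixture of
18 hand-keyed rows.

## Desk-scale study conditions

The published experiments train a GPU-scale model on a private 3206-image
dataset; their absolute IoU tables are not reproducible here and are not
asserted anywhere. Instead the test suite checks desk-scale *properties* on
the synthetic preset, under conditions chosen once and fixed:

* images 64×64, `base_width = 8` ("slim" model, ~1.35M parameters), batch 8;
* Adam with a larger step size for the desk-scale experiments (`1e-2` for the
  overfit run, `3e-2` for the rebalancing runs). The package ships `1e-3` as
  the conservative `train_config()` default, but the overfit sanity diagnostic
  showed that at these problem sizes `1e-3` under-trains badly (20 images
  cannot be memorized in 200 steps, and mid-frequency classes are still
  unlearned after 450 steps), so the experiments use larger step sizes;
* overfit sanity: 20 preset images, 200 steps — training loss must fall by
  ≥90%;
* rebalancing direction: 200 preset images (~150 after background-only
  filtering), uniform vs image-count weights across 3 seeds, compared by the
  rarest class's sensitivity on the training images. In-sample sensitivity is
  the right desk-scale readout: the claim under test is about *learning
  efficiency* on the tail class, and a ~29-image validation split would
  contain at most one or two class-4 images, making the estimate mostly noise.

Small classes emerge in a characteristic order during these runs (background
and class 1 first, class 3 next, classes 2 and 4 last), so the rebalancing
experiment trains just long enough for the tail to be in play; the exact step
budgets are recorded in `tests/testthat/test-acceptance.R`.

## Numerical choices and limitations

* Normalization epsilon `1e-5`, momentum 0.1; biased variance for batch
  statistics, unbiased for the running average.
* Max-pooling and the channel-max plane break ties toward the first index;
  the loss is therefore only piecewise smooth, which matters only for
  finite-difference checks.
* Bilinear upsampling uses half-pixel centres with edge clamping.
* The 6:1 split uses a seeded shuffle and a floor-based cut
  (`floor(n/7)` validation images); background-only images are removed from
  the training split only, since the published filtering is described as a
  training-time step.
* Checkpoints are RDS files containing config, seed, parameters and buffers;
  loading re-validates the configuration.
* The CPU implementation is intended for desk-scale verification, not
  production training: one optimizer step on a batch of eight 64×64 images
  with the slim model takes about a quarter of a second on one core, so a
  200-step run finishes in under a minute; scaling to 256×256 images or
  `base_width = 64` is possible but slow.
* Training trajectories are exactly reproducible for a fixed seed on a fixed
  build, but borderline late-emerging classes can shift by a few epochs across
  BLAS builds, since floating-point summation order differs.
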