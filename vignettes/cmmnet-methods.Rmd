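---
title: "Methods: multi-scale multi-level context networks for biomedical segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-scale multi-level context networks for biomedical segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`cmmnet` implements CMM-Net, a fully convolutional encoder--decoder
segmentation network for 2-D biomedical images.  Its distinguishing
idea, relative to a plain U-Net, is to inject *global* multi-scale
context at *every* contracting level rather than only at the network
bottleneck:

* **Pyramid pooling modules (PPM).**  After each of the first three
  encoder levels, the feature map (with $C$ channels) is adaptively
  average-pooled to $N = 4$ pyramid scales in parallel, each pooled map
  is bottlenecked by a $1{\times}1$ convolution to $C/N$ channels
  (batch normalization, no bias, ReLU), bilinearly upsampled back to
  the level's resolution, and concatenated with the original features.
  The concatenated map therefore has $C + N\,(C/N) = 2C$ channels.
  The smallest scale ($1 \times 1$) is global average pooling; the
  largest defaults to 64 px for dermoscopy-sized inputs, 48 for MR
  slices and 32 for retinal patches.  The PPM output feeds both the
  next encoder level and the matching skip connection, so the decoder
  also sees the pooled global context.
* **Dilated convolutions.**  All $3{\times}3$ convolutions may carry a
  dilation rate $r$, spacing the kernel taps $r-1$ zeros apart at no
  parameter cost:
  $(f *_r w)[x] = \sum_k f[k]\, w[r(x-k)]$.
  Stacking 3x3 stages with doubling rates ending at $r$ grows the
  receptive field to $(2^{r+1}-1)^2$ pixels.  The shipped defaults tie
  the rate to the feature-map size: 6/5/4/3 down the encoder and 4/5/6
  up the decoder for 192-px-scale inputs.

The skeleton is a four-level U-Net: two 3x3 convolutions per encoder
level (widths 32/96/256/512), three 2x2 max poolings, and a decoder of
three 2x bilinear upsamplings each followed by a 3x3 "up-convolution",
concatenation with the skip, and one more 3x3 convolution; a final 3x3
convolution feeds a per-pixel softmax over two classes (class 2 is the
foreground).  Every interior convolution carries a bias and is followed
by batch normalization and ReLU.

### Width calibration

Filter widths are not fully determined by a textual description, so the
width list was calibrated against the two published trainable-parameter
counts that the architecture must reproduce exactly: 10,246,562 for the
dermoscopy/MR configuration (PPM bottleneck 64) and 13,221,794 for the
retinal configuration (bottleneck 128).  An exhaustive search over
width lists (multiples of 8 up to 512) and structural variants found a
*unique* solution: encoder widths (32, 96, 256, 512), the decoder
layout above, a final 3x3 (not 1x1) head without batch normalization,
and bias-free PPM bottleneck convolutions.  Two corroborating facts:
this layout has exactly seven decoder convolutions plus a softmax
stage, matching the published layer inventory, and removing the PPMs
yields 7,271,330 parameters — the "7.3 M" figure quoted for the U-Net
baseline.  `count_parameters()` is a pure function of the
configuration, independent of input size (fully convolutional),
dilation rates and pyramid scales; the test suite asserts all of this.

## Training

Training minimizes the soft dice loss on the foreground probability
$p$ against the binary mask $g$,
$$ L \;=\; 1 - \frac{2\sum p\,g + \epsilon}{\sum p + \sum g + \epsilon},
   \qquad \epsilon = 10^{-6}, $$
with Adam.  The denominator is the sum $|SM| + |GT|$ rather than a set
union: this is the form that makes $L \in [0,1]$ and the exact
complement of the Dice similarity coefficient on binary inputs (a unit
test enforces `dice_loss + DSC/100 = 1`).  The learning rate decays
exponentially per epoch from `initial_learning_rate` (default `1e-4`)
to `initial/lr_reduction_factor` (default factor 10) at the final
epoch; a stepped decay would satisfy the same endpoints, and the smooth
variant was chosen for having no additional free parameter (the step
position).  Canonical settings: 100 epochs, batch 20 for the 2-D image
tasks; 30 epochs, batch 5 for MR slices.

Model selection follows the double cross-validation discipline: the
training split fits the weights, a validation split picks the epoch
snapshot (lowest validation dice loss), and test data are used only
for the final report.  With a fixed schedule seed, runs are bit
reproducible (one named RNG, Mersenne-Twister/Inversion, drives
initialization and shuffling).

Batch normalization uses batch statistics during training and running
statistics (momentum 0.9, $\epsilon = 10^{-5}$) at inference.  Biased
variance is used for both, which matters only at the tiny batch sizes
of the unit tests.

## Augmentation and inversion recovery

The augmentation family is the dihedral group $D_4$: the four
right-angle rotations, optionally preceded by a horizontal flip — the
unique natural 8-element rotation/flip family, applied identically to
image and mask (`eightfold()`), which is how 15,290 training items
become 122,320.  The group is closed and every element has an inverse
in the set; the suite verifies all 64 compositions acting on an
asymmetric array.

Inversion recovery (IR) is the matching test-time scheme: predict on
each of the 8 views, binarize at a threshold (default 0.5 on the
foreground softmax channel), recover each mask with the inverse
transform, and fold everything together with a pixelwise logical OR,
$I_o \leftarrow I_o \,\vert\, \mathrm{IR}(I_k)$.  Binarization must
precede merging because the logical operators are defined on binary
maps.  When several color renderings of one image are evaluated (RGB,
CIELAB, and saturation/value for dermoscopy), the OR runs *within* each
color space and a pixelwise AND combines the per-space results — OR
first is the only order in which the AND can be said to accumulate
per-space results.  OR merging can only grow the foreground, so IR
trades specificity for sensitivity; it is exposed as an option
(`off`, `or_only`, `or_and_colorspaces`) because it demonstrably hurts
tasks with fragmented targets such as whole-tumor MR segmentation.
The SV rendering has two channels but the network expects three; it is
packed as (S, V, V), which preserves the interface without inventing
information.  Color-space copies are treated as additional training
samples, not fused channels.

## Preprocessing pipelines

* **Dermoscopy**: bilinear resize to 192 x 256 (masks resized the same
  way and re-binarized at 0.5).
* **Fundus**: crop to the bounding box of the circular field of view
  (FOV), CLAHE per channel (clip limit 2, 8 x 8 tiles — the method's
  customary defaults; images are replicate-padded to a tile multiple
  and cropped back), values kept in [0, 1].  Scoring is restricted to
  FOV pixels.  Patch handling uses 0-based (row, col) origins with
  half-open 128 x 128 windows, stride 64 for training and 128 for
  testing; when a stride does not tile exactly, the last window is
  anchored to the image edge so coverage is total, and reconstruction
  averages overlaps (exact for non-overlapping grids).
* **MR volumes**: center in-plane crop 240 -> 192 (skull-stripped
  margins are symmetric, so a center crop keeps the brain), channels
  stacked as (T2, FLAIR, T1Gd), min-max normalization per volume and
  per modality, training slices = exactly those with non-empty labels,
  evaluation on all slices re-stacked to a volume and scored as whole
  tumor (`labels > 0`).

All pipeline outputs lie in [0, 1].  Bilinear operations everywhere
(PPM upsampling, decoder upsampling, resizing) use one fixed
convention: half-pixel centers without corner alignment, which
preserves constants and makes same-size resampling an exact identity.
Adaptive average pooling uses floor/ceil bin edges.  In the network
builder, each level's pyramid sizes are clipped to that level's spatial
side (the stand-alone `ppm_forward()` instead rejects oversized
scales); clipping cannot change the parameter count.

## Metrics

All scalar metrics derive from exact pixel contingency counts
(optionally ROI-restricted): sensitivity, specificity, accuracy, Dice,
Jaccard and Matthews correlation, reported as percentages.  Degenerate
denominators return 0 with a warning.  ROC and precision--recall curves
sweep every distinct score; AUC is the trapezoid rule, and the suite
checks it against both a pairwise-ranking oracle and an independent
implementation (pROC).  Multi-item summaries are weighted means with
per-item sample sizes as weights.

## Synthetic phantoms

The generators emulate the three modalities well enough to exercise
every pipeline stage offline, with masks exact by construction:

* `make_lesion()`: one irregular blob (polar-perturbed ellipse with
  random low-order harmonics) on textured skin, darker than its
  surround as dermoscopic lesions are, plus thin dark hair-like
  strokes; default foreground fraction falls in (0.02, 0.5).
* `make_vessels()`: a single branching tree of 1--4 px curves grown
  inside a circular FOV (one connected component by construction);
  vessel fraction within the FOV lies in (0.05, 0.20).
* `make_tumor_volume()`: four correlated pseudo-modalities over an
  elliptical brain, with a bright (in T2/FLAIR/T1Gd) irregular blob in
  a contiguous slab of slices.  The default volume is 240 x 240 x 31 —
  full in-plane size so the 240 -> 192 crop semantics are exercised,
  with a reduced slice count appropriate for desk-scale work.

What the phantoms do *not* model: real lesion/vessel texture
statistics, annotation ambiguity, acquisition artifacts beyond
additive Gaussian noise, or MR physics.  Passing the phantom suite
therefore demonstrates that the machinery (architecture, optimization,
augmentation, IR, metrics, I/O) is correct, not that clinical-grade
accuracy is attained; the published benchmark scores require the
licensed datasets and GPU-scale training and are outside this
package's scope.

## Desk-scale problem sizes

The end-to-end checks use the `phantom` preset: 48 x 64 inputs, reduced
widths 8/16/32/64, PPM bottleneck 8, pyramid 12/4/2/1, and dilation
rates scaled down with the input (2/2/1/1 encoder, 1/2/2 decoder),
mirroring the design rule that rates track feature-map size.  Training
uses 50 easy lesion phantoms (40 fit / 10 validation), 12 epochs,
batch 5, initial learning rate 3e-3 — enough Adam steps for the loss
to converge at this scale.  A reference run of this configuration
reaches a mean held-out Dice of ~0.95; the suite asserts the frozen
regression bound of 0.85.

## Known limitations

* CPU-only: forward/backward passes are im2col convolutions through
  BLAS; fine at phantom scale, not meant for the full benchmark runs.
* Binary segmentation only (`num_classes = 2` is assumed by the dice
  training path and IR's foreground channel).
* Max pooling requires even spatial dims at every level, hence input
  sizes divisible by `2^(levels-1)`.
* The baseline U-Net's published parameter count is quoted only to one
  decimal ("7.3 M"), so the baseline is checked softly, not exactly.
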