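# cmmnet

Semantic segmentation of biomedical images — skin lesions in
dermoscopy, blood vessels in fundus photographs, whole tumors in
multi-modal MR slices — hinges on combining fine local detail with
global context.  `cmmnet` is an R toolkit built around **CMM-Net**
(contextual multi-scale multi-level network): a four-level U-shaped
encoder–decoder that concatenates a **pyramid pooling module** (PPM)
after *every* encoder level, not just the bottleneck, and uses
**dilated convolutions** with level-dependent rates to enlarge
receptive fields at no parameter cost.

For a feature map with $C$ channels, each PPM pools to $N = 4$ scales
(down to $1\times1$ = global average pooling), bottlenecks each scale
to $C/N$ channels with a $1\times1$ convolution, bilinearly upsamples,
and concatenates, giving $2C$ output channels that feed both the next
level and the skip connection.  A $3\times3$ convolution with dilation
rate $r$ spaces its taps $r-1$ zeros apart; cascades with doubling
rates reach a $(2^{r+1}-1)^2$-pixel receptive field.  Training
minimizes the soft dice loss

$$ L = 1 - \frac{2\sum SM\cdot GT + \epsilon}{\sum SM + \sum GT + \epsilon} $$

with Adam and an exponentially decaying learning rate.  At test time
the package offers **inversion recovery** (IR): predict on all eight
rotation/flip views, invert each binarized prediction back to the
original frame, merge with pixelwise logical **OR**, and — when
several color spaces (RGB/LAB/SV) are evaluated — combine the
per-space results with **AND**.

Everything is self-contained: the network forward/backward passes are
hand-implemented (RcppArmadillo im2col convolutions, batch
normalization, bilinear and adaptive-average pooling, softmax, Adam),
and seeded synthetic phantoms (lesions, vessel trees, tumor volumes)
make every stage testable without clinical data.  Evaluation covers
sensitivity/specificity/accuracy, Dice, Jaccard, Matthews correlation,
ROC/PR curves with AUC, and weighted multi-item summaries.

## Worked example

Build the calibrated full-size networks and verify their exact
trainable-parameter counts, then run a complete desk-scale experiment
on synthetic lesion phantoms:

```r
library(cmmnet)

count_parameters(build_cmm_net(preset_config("isic2017")$network))
#> [1] 10246562
count_parameters(build_cmm_net(preset_config("drive")$network))
#> [1] 13221794

pc <- preset_config("phantom", seed = 1)
items <- lapply(1:60, function(i) make_lesion(c(48, 64), "easy", seed = 1000 + i))
imgs <- lapply(items, `[[`, "image")
msks <- lapply(items, `[[`, "mask")

model <- build_cmm_net(pc$network, seed = 1)
model
#> <CMM-Net segmentation model>
#>   input: 48 x 64 x 3, 2 classes
#>   encoder widths: 8/16/32/64
#>   PPM: bottleneck 8, pyramid 12/4/2/1
#>   dilation rates: encoder 2/2/1/1, decoder 1/2/2
#>   trainable parameters: 173,322

fit <- train_segmenter(model, imgs[1:40], msks[1:40], pc$schedule,
                       val_images = imgs[41:50], val_masks = msks[41:50])
round(tail(fit$history, 3), 4)
#>    epoch    lr   loss val_loss
#> 10    10 5e-04 0.0874   0.0875
#> 11    11 4e-04 0.0841   0.0817
#> 12    12 3e-04 0.0796   0.0779

dsc <- sapply(51:60, function(k) {
  pred <- run_ir(fit$model, imgs[[k]])   # OR-merged test-time augmentation
  scalar_metrics(contingency(pred, msks[[k]]))["DSC"]
})
round(mean(dsc), 1)
#> [1] 95
```

The two counts are the exact published calibration targets for the
dermoscopy/MR and retinal configurations; the phantom run trains a
width-reduced CMM-Net for 12 epochs (about half a minute on one CPU)
and reaches a mean held-out Dice of 95% with IR.

A command-line interface wraps the same functions
(`inst/cli/cmmnet.R`):

```sh
Rscript inst/cli/cmmnet.R generate --preset phantom --data-dir data
Rscript inst/cli/cmmnet.R train    --preset phantom --data-dir data --out-dir out
Rscript inst/cli/cmmnet.R evaluate --preset phantom --data-dir data --out-dir out
Rscript inst/cli/cmmnet.R count-params --preset isic2017
```

See `vignettes/cmmnet-methods.Rmd` for the model, the width
calibration, all numerical conventions, and what the phantoms do and
do not emulate.

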