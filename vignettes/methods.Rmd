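---
title: "Segmenting overlapping sheep: model, training recipe and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting overlapping sheep: model, training recipe and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flockseg)
```

## The problem

Sheep in working farm imagery congregate: individuals overlap heavily, and
their fleece gives them wavy, irregular contours. Generic instance
segmentation in the Mask R-CNN family struggles twice over on such scenes —
the detector merges or misses overlapping animals, and the 28 x 28 mask
resolution smears boundary detail into scalloped edges. `flockseg`
implements a two-stage architecture aimed at exactly these two failure
modes: a stronger attention-equipped backbone and detection head for
crowded boxes, and a multi-stage, boundary-aware mask refinement ladder for
contour fidelity.

## The model

**Backbone.** A ConvNeXt-style trunk: a 4x4 stride-4 convolutional stem,
four stages of inverted-bottleneck blocks (7x7 depthwise convolution →
channel layer norm → 1x1 expansion to 4C → GELU → 1x1 projection →
per-channel scale, with a residual), depths (3, 3, 9, 3) and widths
(96, 192, 384, 768). After each stage's last block an efficient channel
attention (ECA) module reweights channels: global average pooling gives a
length-C vector, a 1-D convolution of width

$$k = \left| \frac{\log_2 C}{\gamma} + \frac{b}{\gamma} \right|_{\mathrm{odd}},
\qquad \gamma = 2,\; b = 1$$

(nearest odd integer, ties broken downward) mixes neighbouring channels,
and a sigmoid produces weights in (0, 1). At the four stage widths the rule
gives kernels 3, 5, 5, 5, so the whole mechanism adds only 18 scalars:

```{r}
vapply(c(96, 192, 384, 768), eca_kernel_size, integer(1))
count_backbone_parameters(backbone_config()) -
  count_backbone_parameters(backbone_config(eca_enabled = FALSE))
```

The full backbone sums to `r sprintf("%.3f",
count_backbone_parameters(backbone_config()) / 1e6)` M trainable scalars by
exact per-layer accounting (stem, blocks, downsamplers, ECA kernels; no
classification head). A standard FPN (lateral 1x1 projections, top-down
nearest-neighbour addition, 3x3 smoothing, stride-2 P6) turns the stage
features into a 256-channel pyramid P2..P6 at strides 4..64.

**Detection head.** The second stage departs from the plain two-FC head in
two ways. Structurally, two 3x3 convolutions (width 256, padding 1) are
inserted before a single 1024-wide FC layer — the "2conv+1fc" layout, which
costs only +130,560 parameters over the two-FC baseline, versus +1.18 M for
keeping both FCs and +1.31 M for four convolutions:

```{r}
vapply(c("2conv+1fc", "2conv+2fc", "4conv+1fc"), head_parameter_delta,
       numeric(1))
```

Behaviourally, training uses the dynamic R-CNN strategy: the positive-label
IoU threshold starts at 0.4 and is periodically raised to the mean of the
recorded top-K proposal IoUs (never below 0.4), tracking proposal quality
as it improves; and the SmoothL1 regression loss's beta shrinks toward the
median of recent residual magnitudes (clipped at its initial 1.0),
sharpening the quadratic zone as regression targets concentrate. The
bookkeeping constants (top-K = 75, update every 100 iterations) follow the
defaults of the dynamic R-CNN line of work; only the 0.4 initialization is
a stated design point.

**Segmentation branch.** A semantic head consumes P2: four 3x3
convolutions, a spatial attention module (SAM), and a 1x1 binary
foreground classifier, all without downsampling. SAM concatenates the
channelwise mean and max maps, convolves with a single 7x7 kernel (no
bias) and applies a sigmoid, giving one weight per position; 7 was chosen
over 3 for its larger receptive field. The mask head starts from a 14x14
ROIAlign tile, applies two 3x3 convolutions and SAM, predicts an initial
14x14 mask, then runs three refinement stages: fuse (concatenate instance
features, instance mask logits, ROI-cropped semantic features and semantic
mask, project back to 256 channels with a 1x1 convolution), upsample 2x,
convolve, predict. The ladder is therefore 14 → 28 → 56 → 112.

**Losses.** Total loss is the plain sum L_cls + L_box + L_mask. The mask
term uses mean binary cross-entropy on the first ladder stage and on the
semantic head, and boundary-restricted cross-entropy from the second stage
on: pixels within 2 px (at stage scale) of either the predicted or the
ground-truth contour, a union band recomputed per stage. Stage weights are
equal; the cited refinement design describes the band only qualitatively,
so the width (2 px) and equal weighting are configurable package choices.

## Training recipe

AdamW with base learning rate 5e-4, weight decay 0.05, betas (0.9, 0.999);
100 epochs at batch size 2, stepping the rate down by 10x after epochs 48
and 78. The decay factor is not printed in the recipe this follows; 0.1 is
the convention of the framework that recipe builds on. A 100-iteration
warmup at a tenth of the base rate guards the batch-size-2 start; it is a
package choice, logged in the run config so it can be disabled. Weight
decay applies only to matrix/kernel weights, never to biases, norms or
attention scales.

## Evaluation

COCO-style AP: greedy score-descending matching per IoU threshold (each
ground truth used at most once), 101-point interpolated precision-recall
integration, averaged over thresholds 0.50:0.05:0.95; AP50/AP75 are the
single-threshold values. A detection whose IoU lands exactly on a rung
counts at that rung (matching at >=, the COCO convention). Boundary AP
replaces mask IoU by Boundary IoU: the IoU of the two contour bands, where
a mask's band is the set of its pixels within Euclidean distance d of its
contour, d = 2% of the image diagonal (44 px at 1920x1080), floored at
1 px. Bands are computed with an exact Euclidean distance transform, with
the canvas border counting as contour; the same definitions are tested
against quadratic brute-force oracles. One naming caveat: the source
recipe's prose once describes the stricter single-threshold metric as IoU
0.7 while the standard superscript usage is 0.75; this package reports
AP75 at 0.75.

## Synthetic scenes

The farm dataset this architecture was designed around is not public, so
the package generates scenes with the two properties that make the task
hard, with exact ground truth:

* **Irregular contours.** Each instance is a radial-harmonic blob: vertex
  k at angle 2*pi*k/n has radius R(1 + A * sum_h a_h sin(h theta + phi_h)),
  with harmonic amplitudes normalized so their absolute sum is 1 and
  A < 1, guaranteeing positive radii. Harmonics and phases derive
  deterministically from a texture seed.
* **Controllable overlap.** Pairs of blobs are placed at the center
  distance at which two equal circles reach the requested IoU (solved
  numerically), then rasterized; the achieved mean pairwise IoU is
  attached to each scene and lands within about 0.1 of the target for
  blob pairs.

Occlusion is resolved back-to-front, and annotations are **visible-only**:
occluded pixels are removed, fully hidden instances dropped, and each
annotation's polygons are re-traced from its visible mask with an exact
rectilinear tracer, so re-rasterizing the stored polygons reproduces the
stored mask pixel for pixel (holes included, via doubled zero-width
bridges — the even-odd rule cancels them). Texture is a per-instance gray
level plus speckle, deliberately weak so shape, not intensity, carries the
signal. The generator does not emulate fleece texture, shadows, motion
blur or perspective; a model passing the synthetic suite has demonstrated
that the architecture and optimization work, not that it transfers to
farm imagery.

Default generation conditions: 256x256 canvases, 1–10 instances per scene
(the crowding range the task targets), overlap targets up to 0.3, and
flat/gradient/noise backgrounds with illumination gain 1.

## Augmentation

Copy-Paste composites donor instances onto host scenes (hard paste, no
blending; occluded host annotations are recomputed, sub-10 px remnants
dropped). Scale jittering resizes isotropically — 0.8–1.25 for the
standard range, 0.1–2.0 for the large range — then crops (random top-left
anchor) or pads to a square canvas; the pad value is mid-gray 128, since
"gray" is otherwise unquantified. Horizontal flips apply with probability
0.5, and normalization uses the conventional per-channel statistics. Every
augmented record re-derives polygons from transformed masks, so augmented
ground truth stays exact by construction.

## Numerical and engineering choices

* All layers carry hand-written reverse-mode gradients (arrays, BLAS
  matrix products, im2col with cached index matrices); every layer is
  verified against central finite differences in the test suite.
* ROIAlign samples one bilinear point per bin at the bin center (the
  aligned, half-pixel-offset convention); level assignment follows the
  standard floor(4 + log2(sqrt(area)/224)) rule clamped to P2..P5.
* The ECA convolution has no bias — required for the sigma(0) = 0.5
  zero-input identity — and layer scale initializes at 1e-6; stochastic
  depth is off at this scale.
* Mask ground truth is rasterized per stage directly from the instance
  polygons inside the detection box, avoiding compounded interpolation.
* Inference binarizes at probability 0.5 and pastes the 112x112 tile into
  the detection box with bilinear resizing.
* Stage-2 training proposals include the ground-truth boxes plus four
  jittered copies each (8% box-size noise), the long-standing stabilizer
  for small runs: the regression loss then sees a stable positive
  population from the first iteration instead of switching on when the
  first RPN proposal crosses the IoU threshold. Positives are sampled at
  the standard 0.25 fraction, best IoU first; negatives are taken
  deterministically as the hardest (highest-IoU) ones, which removes
  sampling variance from the per-iteration loss. Regression targets are
  the raw encoded deltas — the per-coordinate 0.1/0.2 target
  normalization some frameworks apply rescales newly admitted mid-IoU
  positives' targets by 5–10x and with it the early loss curve; dropped
  here.
* Degenerate guards: empty masks signal a typed condition rather than a
  zero box; degenerate ROIs return zero features with a warning; an
  annotation must keep at least 10 visible pixels to survive augmentation.

## Desk-scale configuration

The package trains the full architecture end to end on CPU. The
`tiny_model_config()` used by the test suite keeps every structural
element (stage layout, attention placement, ladder sizes, dynamic
strategies) but shrinks widths: backbone depths (1, 1, 2, 1) at widths
(32, 64, 128, 256), a 48-channel pyramid and 192-wide FC. The end-to-end
property run overfits one 256x256 two-instance scene for 150 iterations at
batch size 1 with a short ten-iteration warmup — enough for the loss to fall
monotonically early on and for the trained model to re-detect and
re-segment its own training scene at high mask AP50. Parameter-count
checks always use the full-width configuration; they are resolution-free
arithmetic. Published-scale accuracy on real imagery is out of scope: it
requires the non-public farm dataset and GPU-scale training.

## Known limitations

* One foreground category; crowd regions (iscrowd = 1) pass through I/O
  but are not used for training.
* Compressed RLE segmentations are not parsed (uncompressed counts and
  polygons are); images are read and written as PNG.
* The CPU implementation is desk-scale: full-width training at
  1024-pixel resolution is arithmetically correct but impractically slow.
* The synthetic generator's best-effort overlap placement dilutes for
  many-instance scenes (pairwise mean falls below the target as distant
  pairs accumulate); it warns when it misses by more than 0.2.
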