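# flockseg

Two-stage instance segmentation of overlapping sheep, in pure R.

Crowded flocks are hard for computer vision: animals overlap heavily and
fleece makes their contours irregular, so generic Mask R-CNN-style models
merge neighbouring individuals and smear boundaries. `flockseg` implements,
trains and evaluates an architecture aimed at both failure modes:

* **ConvNeXt-style backbone with efficient channel attention (ECA)** —
  depths (3, 3, 9, 3), widths (96, 192, 384, 768), one ECA module per
  stage whose 1-D kernel width adapts to the channel count,
  k = |log2(C)/2 + 1/2|_odd, giving kernels (3, 5, 5, 5) and an overhead
  of just 18 scalars on a 27.8 M-parameter trunk; FPN neck (P2..P6).
* **Improved dynamic detection head** — two 3x3 convolutions before a
  single 1024-wide FC (+0.13 M parameters over the two-FC baseline),
  dynamic label assignment (IoU threshold rising from 0.4) and dynamic
  SmoothL1 regression.
* **Boundary-refined mask head with spatial attention** — a semantic head
  on P2, semantic fusion at each stage, and a mask ladder that doubles
  14 → 28 → 56 → 112 under a boundary-aware loss restricted to contour
  bands from the second stage on.
* **Copy-Paste and large-scale-jitter augmentation**, COCO JSON I/O, and
  **COCO AP + Boundary AP** evaluation (boundary bands at d = 2% of the
  image diagonal, exact Euclidean distance transform).
* A **synthetic scene generator** producing overlapping irregular-contour
  instances with pixel-exact COCO annotations, standing in for the
  non-public farm imagery.

Every network layer carries a hand-written reverse-mode gradient
(finite-difference-verified), so the whole pipeline trains end to end on a
CPU at desk scale.

## Worked example

```r
library(flockseg)

# the adaptive attention kernel at the four stage widths
vapply(c(96, 192, 384, 768), eca_kernel_size, integer(1))
#> [1] 3 5 5 5

# exact backbone parameter accounting (full-width configuration)
n <- count_backbone_parameters(backbone_config())
sprintf("%.3f M", n / 1e6)
#> [1] "27.819 M"
n - count_backbone_parameters(backbone_config(eca_enabled = FALSE))
#> [1] 18

# detector-head cost of the 2conv+1fc layout vs the 2-FC baseline
head_parameter_delta("2conv+1fc")
#> [1] 130560

# a 6:2:2 split of 1396 image ids
lengths(split_dataset(seq_len(1396), c(6, 2, 2), seed = 0))
#> train   val  test
#>   838   279   279

# generate a small synthetic dataset and train the desk-scale model
records <- generate_dataset(4, seed = 1)
set.seed(1)
model <- build_segmenter(tiny_model_config())
state <- train(model, records,
               run_config(seed = 1, warmup_iters = 20L, batch_size = 1L),
               n_iter = 20L)
tail(state$history$total, 1)   # total multi-task loss after 20 iterations

# evaluate: box / mask / boundary AP
evaluate(model, records)
```

The first four results are architecture arithmetic and print exactly the
values shown; the training loss depends on the seed and iteration count.
The kernel sizes mean each stage mixes only 3–5 neighbouring channels when
computing attention weights; the 18-scalar overhead is why the
attention-equipped backbone costs essentially nothing over its plain
counterpart; 130,560 is the full price of the two extra shared
convolutions once the second FC layer is removed.

A command-line front end wrapping the same functions ships in
`inst/cli/flockseg.R` (`generate`, `split`, `params`, `train`, `evaluate`,
`augment-preview`).

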