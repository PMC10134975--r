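test_that("box encode/decode is an algebraic inverse", {
  set.seed(9)
  anchors <- cbind(runif(40, 0, 50), runif(40, 0, 50), 0, 0)
  anchors[, 3] <- anchors[, 1] + runif(40, 5, 30)
  anchors[, 4] <- anchors[, 2] + runif(40, 5, 30)
  boxes <- anchors + matrix(rnorm(160, 0, 2), 40, 4)
  boxes[, 3] <- pmax(boxes[, 3], boxes[, 1] + 1)
  boxes[, 4] <- pmax(boxes[, 4], boxes[, 2] + 1)
  dec <- bbox_decode(bbox_encode(boxes, anchors), anchors)
  expect_equal(dec, unname(boxes), tolerance = 1e-10)
})

test_that("zero RPN logits give uniform 0.5 scores and clipped proposals", {
  set.seed(12)
  pyr <- list(P2 = array(rnorm(16 * 16 * 8), c(16, 16, 8)),
              P3 = array(rnorm(8 * 8 * 8), c(8, 8, 8)),
              P4 = array(rnorm(4 * 4 * 8), c(4, 4, 8)),
              P5 = array(rnorm(2 * 2 * 8), c(2, 2, 8)),
              P6 = array(rnorm(1 * 1 * 8), c(1, 1, 8)))
  outs <- lapply(pyr, function(p) {
    list(cls = array(0, c(dim(p)[1], dim(p)[2], 3)),
         reg = array(0, c(dim(p)[1], dim(p)[2], 12)))
  })
  expect_equal(unique(as.vector(flockseg:::sigmoid(
    flockseg:::flatten_rpn_cls(outs$P2$cls)))), 0.5)
  props <- rpn_proposals(outs, pyr, img_w = 64, img_h = 64, pre_nms = 100,
                         post_nms = 50)
  expect_true(all(props$boxes[, c(1, 3)] >= 0 & props$boxes[, c(1, 3)] <= 64))
  expect_true(all(props$boxes[, c(2, 4)] >= 0 & props$boxes[, c(2, 4)] <= 64))
  expect_true(all(props$boxes[, 3] > props$boxes[, 1]))
})

test_that("ROIAlign interpolates constants exactly and matches bilinear", {
  pyr <- list(P2 = array(3.25, c(16, 16, 4)), P3 = array(0, c(8, 8, 4)),
              P4 = array(0, c(4, 4, 4)), P5 = array(0, c(2, 2, 4)),
              P6 = array(0, c(1, 1, 4)))
  ra <- roi_align(pyr, c(5, 5, 40, 30), 7, level = 1L)
  expect_equal(dim(ra$feat), c(7, 7, 4))
  expect_equal(max(abs(ra$feat - 3.25)), 0)
  # pointwise bilinear oracle on a random map
  set.seed(21)
  f <- array(rnorm(16 * 16), c(16, 16, 1))
  pyr$P2 <- f
  box <- c(6, 4, 30, 28)
  ra <- roi_align(pyr, box, 3, level = 1L)
  stride <- 4
  for (i in 1:3) {
    for (j in 1:3) {
      x <- (box[1] + (j - 0.5) * (box[3] - box[1]) / 3) / stride - 0.5
      y <- (box[2] + (i - 0.5) * (box[4] - box[2]) / 3) / stride - 0.5
      x0 <- floor(x); y0 <- floor(y)
      wx <- x - x0; wy <- y - y0
      val <- f[y0 + 1, x0 + 1, 1] * (1 - wy) * (1 - wx) +
        f[y0 + 1, x0 + 2, 1] * (1 - wy) * wx +
        f[y0 + 2, x0 + 1, 1] * wy * (1 - wx) +
        f[y0 + 2, x0 + 2, 1] * wy * wx
      expect_equal(ra$feat[i, j, 1], val, tolerance = 1e-12)
    }
  }
  expect_warning(roi_align(pyr, c(5, 5, 5, 5), 7, level = 1L), "degenerate")
})

test_that("the box head emits background+sheep logits and per-class deltas", {
  cfg <- detector_config(roi_channels = 16L, fc_width = 32L)
  set.seed(2)
  for (layout in c("2fc", "2conv+1fc", "2conv+2fc", "4conv+1fc")) {
    cfg$head_layout <- layout
    bh <- build_box_head(cfg)
    out <- bh$forward(array(rnorm(7 * 7 * 16), c(7, 7, 16)))
    expect_length(out$cls, 2)
    expect_length(out$reg, 4)
  }
  # zero ROI with zero-initialized predictors gives zero deltas
  bh <- build_box_head(cfg)
  bh$submodules$reg$params$weight$value[] <- 0
  out <- bh$forward(array(0, c(7, 7, 16)))
  expect_equal(max(abs(out$reg)), 0)
})

test_that("head parameter deltas equal the published +0.13/+1.18/+1.31 M", {
  expect_identical(head_parameter_delta("2conv+1fc"), 130560)
  expect_identical(head_parameter_delta("2conv+2fc"), 1180160)
  expect_identical(head_parameter_delta("4conv+1fc"), 1310720)
  expect_equal(head_parameter_delta("2fc"), 0)
  # agreement with instantiated heads at full width (trunk = all but the
  # two predictor linears, which are shared across layouts)
  trunk_params <- function(layout) {
    cfg <- detector_config(head_layout = layout)
    bh <- build_box_head(cfg)
    preds <- length(bh$submodules$cls$params$weight$value) +
      length(bh$submodules$cls$params$bias$value) +
      length(bh$submodules$reg$params$weight$value) +
      length(bh$submodules$reg$params$bias$value)
    module_n_parameters(bh) - preds
  }
  base <- trunk_params("2fc")
  expect_identical(trunk_params("2conv+1fc") - base, 130560)
  expect_identical(trunk_params("2conv+2fc") - base, 1180160)
  expect_identical(trunk_params("4conv+1fc") - base, 1310720)
})

test_that("dynamic label assignment starts at 0.4 and tracks proposal quality", {
  cfg <- detector_config(label_update_interval = 5L, label_topk = 2L)
  st <- dynamic_state(cfg)
  expect_equal(st$threshold, 0.4)
  la <- dynamic_label_assign(c(0.9, 0.5, 0.3), st)
  expect_equal(la$labels, c(TRUE, TRUE, FALSE))
  # constant IoU 0.8 for one full interval moves the threshold to 0.8
  st <- dynamic_state(cfg)
  for (i in 1:5) st <- dynamic_label_assign(c(0.8, 0.8, 0.8), st)$state
  expect_equal(st$threshold, 0.8)
  # empty proposal set: all-negative labels
  expect_length(dynamic_label_assign(numeric(0), st)$labels, 0)
})

test_that("the dynamic threshold never decreases under improving proposals", {
  cfg <- detector_config(label_update_interval = 3L, label_topk = 1L)
  st <- dynamic_state(cfg)
  thresholds <- st$threshold
  quality <- seq(0.3, 0.9, length.out = 30)
  for (q in quality) {
    st <- dynamic_label_assign(c(q, q / 2), st)$state
    thresholds <- c(thresholds, st$threshold)
  }
  expect_true(all(diff(thresholds) >= -1e-12))
  expect_gte(min(thresholds), cfg$iou_init)
})

test_that("dynamic SmoothL1 is continuous and sharpens as beta shrinks", {
  expect_equal(dynamic_smooth_l1(0, 1)$loss, 0)
  for (beta in c(0.2, 1, 2)) {
    lo <- dynamic_smooth_l1(beta - 1e-9, beta)$loss
    hi <- dynamic_smooth_l1(beta + 1e-9, beta)$loss
    expect_equal(lo, 0.5 * beta, tolerance = 1e-6)
    expect_equal(hi, 0.5 * beta, tolerance = 1e-6)
  }
  # finite-difference gradient at r = 0.05 grows when beta drops 1.0 -> 0.2
  fd <- function(beta) {
    (dynamic_smooth_l1(0.05 + 1e-6, beta)$loss -
       dynamic_smooth_l1(0.05 - 1e-6, beta)$loss) / 2e-6
  }
  expect_gt(fd(0.2), fd(1.0))
  expect_equal(fd(1.0), dynamic_smooth_l1(0.05, 1.0)$grad, tolerance = 1e-4)
  # beta = 1 reduces to the standard SmoothL1
  r <- seq(-3, 3, by = 0.25)
  std <- ifelse(abs(r) < 1, 0.5 * r^2, abs(r) - 0.5)
  expect_equal(vapply(r, function(v) dynamic_smooth_l1(v, 1)$loss, numeric(1)),
               std)
  expect_error(dynamic_smooth_l1(1, 0), "positive")
})

test_that("beta updates clip at the initial value and follow the median", {
  cfg <- detector_config(beta_update_interval = 2L, beta_init = 1)
  st <- dynamic_state(cfg)
  st$iter <- 1L
  st <- dynamic_beta_update(st, c(0.1, 0.2, 0.3))
  st$iter <- 2L
  st <- dynamic_beta_update(st, c(0.3, 0.4, 0.5))
  expect_equal(st$beta, stats::median(c(0.2, 0.4)))
  st$iter <- 4L
  st$beta_record <- c(5, 7)
  st <- dynamic_beta_update(st, numeric(0))
  expect_equal(st$beta, 1)   # clipped to beta_init
})
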