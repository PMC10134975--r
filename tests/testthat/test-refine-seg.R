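test_that("spatial attention weights match the direct oracle", {
  set.seed(17)
  for (i in 1:50) {
    C <- sample(2:8, 1)
    k <- sample(c(3, 7), 1)
    X <- array(rnorm(9 * 8 * C), c(9, 8, C))
    kern <- array(rnorm(k * k * 2, sd = 0.3), c(k, k, 2))
    expect_equal(sam_weights(X, kern), oracle_sam_weights(X, kern),
                 tolerance = 1e-6)
  }
  X0 <- array(0, c(5, 6, 4))
  w <- sam_weights(X0, array(rnorm(9 * 2), c(3, 3, 2)))
  expect_equal(dim(w), c(5, 6))
  expect_equal(unique(as.vector(w)), 0.5)
  expect_error(sam_weights(X0, array(0, c(4, 4, 2))), "odd")
})

test_that("spatial reweighting stays in (0,1) and never amplifies", {
  set.seed(4)
  sam <- flockseg:::layer_sam(7)
  X <- array(rnorm(10 * 10 * 6), c(10, 10, 6))
  Y <- sam$forward(X)
  expect_true(all(abs(Y) <= abs(X) + 1e-12))
})

test_that("the semantic head preserves resolution and supports a SAM bypass", {
  cfg <- segmentation_config(channels = 8L)
  set.seed(6)
  sh <- build_semantic_head(cfg)
  p2 <- array(rnorm(12 * 10 * 8), c(12, 10, 8))
  out <- sh$forward(p2)
  expect_equal(dim(out$logits)[1:2], c(12, 10))
  expect_equal(dim(out$features)[1:2], c(12, 10))
  probs <- flockseg:::sigmoid(out$logits)
  expect_true(all(probs > 0 & probs < 1))
  # disabling SAM reduces to the plain conv stack (weights identically 1)
  cfg2 <- segmentation_config(channels = 8L, sam_enabled = FALSE)
  sh2 <- build_semantic_head(cfg2)
  sd_full <- state_dict(sh)
  load_state_dict(sh2, sd_full[setdiff(names(sd_full),
                                       grep("^sam", names(sd_full),
                                            value = TRUE))])
  out2 <- sh2$forward(p2)
  # pre-attention conv stack output, reweighted by the SAM map, equals the
  # attention head's features
  w <- sam_weights(out2$features, sh$submodules$sam$submodules$conv$params$weight$value)
  expect_equal(out$features, sweep(out2$features, c(1, 2), w, "*"),
               tolerance = 1e-10)
})

test_that("semantic fusion concatenates and projects as specified", {
  set.seed(13)
  sfm <- build_sfm(6L)
  fi <- array(rnorm(5 * 5 * 6), c(5, 5, 6))
  mi <- array(rnorm(5 * 5), c(5, 5, 1))
  fs <- array(rnorm(5 * 5 * 6), c(5, 5, 6))
  ms <- array(rnorm(5 * 5), c(5, 5, 1))
  out <- sfm_fuse(sfm, fi, mi, fs, ms)
  expect_equal(dim(out), c(5, 5, 6))
  # concat -> 1x1 conv -> relu oracle
  x <- array(c(fi, mi, fs, ms), c(5, 5, 14))
  wt <- sfm$submodules$proj$params$weight$value
  bs <- sfm$submodules$proj$params$bias$value
  manual <- array(0, c(5, 5, 6))
  for (o in 1:6) {
    acc <- matrix(bs[o], 5, 5)
    for (ci in 1:14) acc <- acc + x[, , ci] * wt[1, 1, ci, o]
    manual[, , o] <- pmax(acc, 0)
  }
  expect_equal(out, manual, tolerance = 1e-10)
  # zero semantic inputs: output depends only on the instance inputs
  z6 <- array(0, c(5, 5, 6)); z1 <- array(0, c(5, 5, 1))
  a <- sfm_fuse(sfm, fi, mi, z6, z1)
  fi2 <- fi; fi2[1, 1, 1] <- fi2[1, 1, 1] + 1
  b <- sfm_fuse(sfm, fi2, mi, z6, z1)
  expect_false(isTRUE(all.equal(a, b)))
  expect_error(sfm$forward(fi, mi, array(0, c(4, 4, 6)), ms), "spatial")
})

test_that("the refinement ladder strictly doubles to 112", {
  expect_equal(mask_stage_sizes(segmentation_config()), c(14, 28, 56, 112))
  cfg <- segmentation_config(channels = 8L)
  set.seed(19)
  mh <- build_mask_head(cfg)
  roi <- array(rnorm(14 * 14 * 8), c(14, 14, 8))
  sizes <- mask_stage_sizes(cfg)
  sf <- lapply(sizes[1:3], function(s) array(rnorm(s * s * 8), c(s, s, 8)))
  sm <- lapply(sizes[1:3], function(s) array(rnorm(s * s), c(s, s, 1)))
  stack <- mh$forward(roi, sf, sm)
  expect_equal(vapply(stack, function(x) dim(x)[1], numeric(1)),
               c(14, 28, 56, 112))
  expect_true(all(is.finite(unlist(stack))))
  expect_equal(dim(stack[[4]])[1], 8 * dim(stack[[1]])[1] / 1)
})

test_that("boundary regions agree with the brute-force distance oracle", {
  set.seed(23)
  for (i in 1:20) {
    m <- random_mask(16, 16, runif(1, 0.2, 0.7))
    w <- sample(1:3, 1)
    expect_identical(unname(boundary_region(m, w)),
                     unname(oracle_boundary_region(m, w)),
                     label = paste("mask", i))
  }
  # full-canvas mask: a frame of the requested width
  full <- matrix(TRUE, 12, 12)
  fr <- boundary_region(full, 2)
  expect_identical(unname(fr), unname(oracle_boundary_region(full, 2)))
  expect_true(all(fr[1:2, ]) && all(fr[11:12, ]) &&
                all(fr[, 1:2]) && all(fr[, 11:12]))
  expect_false(fr[6, 6])
  # a one-pixel-wide line is contained in its own boundary region
  line <- matrix(FALSE, 10, 10); line[5, 2:9] <- TRUE
  expect_true(all(boundary_region(line, 1)[line]))
  expect_equal(sum(boundary_region(matrix(FALSE, 6, 6), 1)), 0)
  expect_error(boundary_region(full, 0), "width_px")
})

test_that("refinement losses vanish at perfection and localize later stages", {
  sizes <- c(8, 16, 32)
  gts <- lapply(sizes, function(s) {
    m <- matrix(FALSE, s, s); m[2:(s / 2), 2:(s / 2)] <- TRUE; m
  })
  perfect <- lapply(gts, function(g) array(ifelse(g, 30, -30), c(dim(g), 1)))
  out <- refinement_losses(perfect, gts)
  expect_lt(out$total, 1e-10)
  # uniform 0.5 prediction: stage-1 BCE is exactly ln 2 per pixel
  flat <- lapply(gts, function(g) array(0, c(dim(g), 1)))
  out2 <- refinement_losses(flat, gts)
  expect_equal(unname(out2$components["stage1"]), log(2))
  expect_true(all(out2$components >= 0))
  # with a band wider than the tile diagonal, restricted BCE == full BCE
  g <- gts[[2]]
  lg <- array(rnorm(16 * 16), c(16, 16, 1))
  wide <- refinement_losses(list(array(0, c(8, 8, 1)), lg),
                            list(gts[[1]], g), bar_width = 32L)
  full_bce <- mean(flockseg:::bce_with_logits(matrix(lg, 16, 16), g * 1)$loss)
  expect_equal(unname(wide$components["stage2"]), full_bce, tolerance = 1e-12)
})

test_that("semantic supervision contributes a mean BCE at P2 resolution", {
  sl <- array(rnorm(10 * 10), c(10, 10, 1))
  gt <- random_mask(10, 10, 0.5, seed = 2)
  out <- refinement_losses(list(array(0, c(4, 4, 1))), list(matrix(FALSE, 4, 4)),
                           semantic_logits = sl, gt_semantic = gt)
  expect_equal(unname(out$components["semantic"]),
               mean(flockseg:::bce_with_logits(matrix(sl, 10, 10), gt * 1)$loss))
  expect_equal(dim(out$grads$semantic), dim(sl))
})
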