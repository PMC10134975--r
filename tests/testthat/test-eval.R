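test_that("precision and recall follow the counting formulas", {
  expect_equal(unname(precision_recall(3, 1, 0)["precision"]), 0.75)
  expect_equal(unname(precision_recall(5, 0, 5)["recall"]), 0.5)
  expect_equal(unname(precision_recall(0, 0, 0)), c(0, 0))
  expect_error(precision_recall(-1, 0, 0), "non-negative")
})

test_that("mask IoU matches a pixel-loop oracle", {
  A <- random_mask(10, 10, 0.5, seed = 1)
  expect_equal(mask_iou(A, A), 1)
  B <- matrix(FALSE, 10, 10); B[1:3, 1:3] <- TRUE
  C <- matrix(FALSE, 10, 10); C[6:9, 6:9] <- TRUE
  expect_equal(mask_iou(B, C), 0)
  expect_equal(mask_iou(matrix(FALSE, 4, 4), matrix(FALSE, 4, 4)), 0)
  set.seed(30)
  for (i in 1:20) {
    A <- random_mask(8, 9, runif(1, 0.2, 0.8))
    B <- random_mask(8, 9, runif(1, 0.2, 0.8))
    expect_equal(mask_iou(A, B), oracle_mask_iou(A, B))
  }
  expect_error(mask_iou(A, matrix(FALSE, 3, 3)), "canvas")
})

test_that("boundary IoU matches the brute-force band oracle", {
  sq <- matrix(FALSE, 64, 64); sq[20:39, 20:39] <- TRUE
  shifted <- matrix(FALSE, 64, 64); shifted[22:41, 20:39] <- TRUE
  got <- boundary_iou(sq, shifted, 2)
  bb <- oracle_boundary_band(sq, 2)
  pb <- oracle_boundary_band(shifted, 2)
  expect_equal(got, sum(bb & pb) / sum(bb | pb))
  expect_equal(boundary_iou(sq, sq, 2), 1)
  disj <- matrix(FALSE, 64, 64); disj[50:60, 50:60] <- TRUE
  expect_equal(boundary_iou(sq, disj, 2), 0)
  set.seed(41)
  for (i in 1:30) {
    A <- random_mask(14, 14, runif(1, 0.3, 0.6))
    B <- random_mask(14, 14, runif(1, 0.3, 0.6))
    d <- sample(1:3, 1)
    bb <- oracle_boundary_band(A, d); pb <- oracle_boundary_band(B, d)
    expected <- if (sum(bb | pb) == 0) 0 else sum(bb & pb) / sum(bb | pb)
    expect_equal(boundary_iou(A, B, d), expected, tolerance = 1e-12)
    expect_equal(boundary_iou(A, B, d), boundary_iou(B, A, d))
  }
})

test_that("identity and thin-object properties of boundary IoU hold", {
  set.seed(52)
  for (i in 1:10) {
    A <- random_mask(12, 12, 0.5)
    if (!any(A)) next
    for (d in c(1, 3, 12)) expect_equal(boundary_iou(A, A, d), 1)
  }
  # objects entirely within d of their contour: boundary IoU == mask IoU
  for (i in 1:10) {
    A <- matrix(FALSE, 32, 32); B <- matrix(FALSE, 32, 32)
    A[sample(4:24, 1) + 0:7, sample(4:24, 1) + 0:7] <- TRUE
    B[sample(4:24, 1) + 0:7, sample(4:24, 1) + 0:7] <- TRUE
    expect_equal(boundary_iou(A, B, 8), mask_iou(A, B))
  }
})

test_that("boundary width is 2% of the diagonal with a 1 px floor", {
  expect_equal(boundary_width(1920, 1080), 44L)
  expect_equal(boundary_width(300, 400), 10L)
  expect_gte(boundary_width(10, 10), 1L)
})

test_that("single-detection AP follows the threshold ladder exactly", {
  gt <- list(list(image_id = 1, obj = c(0, 0, 10, 10)))
  perfect <- list(list(image_id = 1, score = 0.9, obj = c(0, 0, 10, 10)))
  ap <- average_precision(perfect, gt, box_iou)
  expect_equal(unname(ap), c(1, 1, 1))
  # IoU 0.58: passes the 0.50 and 0.55 rungs only -> AP = 2/10
  det6 <- list(list(image_id = 1, score = 0.9, obj = c(0, 0, 10, 5.8)))
  ap6 <- average_precision(det6, gt, box_iou)
  expect_equal(unname(ap6["AP50"]), 1)
  expect_equal(unname(ap6["AP75"]), 0)
  expect_equal(unname(ap6["AP"]), 0.2)
  # an IoU landing exactly on a rung counts at that rung (match at >=)
  det60 <- list(list(image_id = 1, score = 0.9, obj = c(0, 0, 10, 6)))
  expect_equal(unname(average_precision(det60, gt, box_iou)["AP"]), 0.3)
  # no ground truth: flagged degenerate zero
  apd <- average_precision(perfect, list(), box_iou)
  expect_true(attr(apd, "degenerate"))
  expect_equal(unname(apd["AP"]), 0)
})

test_that("AP is non-increasing in the IoU threshold", {
  set.seed(61)
  gts <- list(); dets <- list()
  for (img in 1:4) {
    for (k in 1:3) {
      x <- runif(1, 0, 40); y <- runif(1, 0, 40)
      w <- runif(1, 8, 20); h <- runif(1, 8, 20)
      gts[[length(gts) + 1]] <- list(image_id = img, obj = c(x, y, x + w, y + h))
      jit <- rnorm(4, 0, 2)
      dets[[length(dets) + 1]] <- list(image_id = img, score = runif(1),
                                       obj = c(x, y, x + w, y + h) + jit)
    }
  }
  thr <- seq(0.5, 0.95, 0.05)
  per_thr <- vapply(thr, function(t) {
    unname(average_precision(dets, gts, box_iou, thresholds = t)["AP"])
  }, numeric(1))
  expect_true(all(diff(per_thr) <= 1e-12))
})

test_that("the evaluator reproduces an independent implementation", {
  set.seed(71)
  records <- generate_dataset(5, spec_fn = function(i) {
    scene_spec(width = 64, height = 64, n_instances = 3, overlap_target = 0.1)
  }, seed = 15)
  gts <- list(); dets <- list()
  for (r in records) {
    for (inst in r$instances) {
      m <- polygons_to_mask(inst$polygons, r$height, r$width)
      gts[[length(gts) + 1]] <- list(image_id = r$image_id, obj = m)
      # jittered prediction: random shift of the gt mask, random score
      dy <- sample(-3:3, 1); dx <- sample(-3:3, 1)
      pm <- matrix(FALSE, r$height, r$width)
      src <- which(m, arr.ind = TRUE)
      dst <- cbind(src[, 1] + dy, src[, 2] + dx)
      ok <- dst[, 1] >= 1 & dst[, 1] <= r$height &
        dst[, 2] >= 1 & dst[, 2] <= r$width
      pm[dst[ok, , drop = FALSE]] <- TRUE
      dets[[length(dets) + 1]] <- list(image_id = r$image_id,
                                       score = runif(1), obj = pm)
    }
    # plus one false positive per image
    fp <- matrix(FALSE, r$height, r$width); fp[1:6, 1:6] <- TRUE
    dets[[length(dets) + 1]] <- list(image_id = r$image_id,
                                     score = runif(1, 0, 0.3), obj = fp)
  }
  mine <- average_precision(dets, gts, mask_iou)
  ref <- oracle_average_precision(dets, gts, mask_iou)
  expect_equal(unname(mine["AP"]), mean(ref), tolerance = 1e-4)
  expect_equal(unname(mine["AP50"]), unname(ref["0.50"]), tolerance = 1e-4)
  expect_equal(unname(mine["AP75"]), unname(ref["0.75"]), tolerance = 1e-4)
})

test_that("eval_report scores ground truth fed back as perfect predictions", {
  records <- generate_dataset(2, spec_fn = function(i) {
    scene_spec(width = 48, height = 48, n_instances = 2, overlap_target = 0.1)
  }, seed = 33)
  preds <- list()
  for (r in records) {
    for (inst in r$instances) {
      m <- polygons_to_mask(inst$polygons, r$height, r$width)
      bb <- inst$bbox
      preds[[length(preds) + 1]] <- list(
        image_id = r$image_id, score = 1,
        box = c(bb[1], bb[2], bb[1] + bb[3], bb[2] + bb[4]), mask = m)
    }
  }
  rep <- eval_report(preds, records)
  expect_equal(rep$AP, rep(1, 3))
  expect_equal(rep$AP50, rep(1, 3))
  # empty predictions: all zeros
  rep0 <- eval_report(list(), records)
  expect_equal(rep0$AP, rep(0, 3))
})
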