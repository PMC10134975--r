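# Full two-stage model: backbone + FPN + RPN + box head + semantic/mask
# heads, with a hand-rolled backward pass threading gradients from every
# loss back to the image stem. One image per forward; batches accumulate
# gradients across images before an optimizer step.

#' Model configuration
#'
#' @param backbone a [backbone_config()].
#' @param fpn_channels pyramid width (256 full scale; small configs shrink
#'   it together with the head widths).
#' @param detector a [detector_config()].
#' @param segmentation a [segmentation_config()].
#' @param pixel_mean,pixel_std normalization statistics.
#' @return a `model_config` list.
#' @export
model_config <- function(backbone = backbone_config(),
                         fpn_channels = 256L,
                         detector = detector_config(),
                         segmentation = segmentation_config(),
                         pixel_mean = c(123.675, 116.28, 103.53),
                         pixel_std = c(58.395, 57.12, 57.375)) {
  structure(list(backbone = backbone, fpn_channels = as.integer(fpn_channels),
                 detector = detector, segmentation = segmentation,
                 pixel_mean = pixel_mean, pixel_std = pixel_std),
            class = "model_config")
}

#' Reduced configuration for CPU-scale experiments
#'
#' Tiny backbone, a narrow pyramid and narrow heads; the architecture (stage
#' structure, attention placement, ladder sizes) is unchanged.
#' @return a `model_config` list.
#' @export
tiny_model_config <- function() {
  model_config(
    backbone = tiny_backbone_config(),
    fpn_channels = 48L,
    detector = detector_config(roi_channels = 48L, fc_width = 192L),
    segmentation = segmentation_config(channels = 48L))
}

#' Build the full segmentation model
#'
#' @param config a [model_config()].
#' @return an `fs_module` with submodules backbone, fpn, rpn, box_head,
#'   semantic_head, mask_head.
#' @export
build_segmenter <- function(config) {
  sub <- list(
    backbone = build_backbone(config$backbone),
    fpn = build_fpn(config$backbone$widths, config$fpn_channels),
    rpn = build_rpn(config$fpn_channels),
    box_head = build_box_head(config$detector),
    semantic_head = build_semantic_head(config$segmentation),
    mask_head = build_mask_head(config$segmentation))
  m <- fs_module("segmenter", submodules = sub)
  m$config <- config
  m
}

# ground-truth boxes (x1,y1,x2,y2) from a record
gt_boxes <- function(record) {
  if (!length(record$instances)) return(matrix(0, 0, 4))
  t(vapply(record$instances, function(i) {
    b <- i$bbox
    c(b[1], b[2], b[1] + b[3], b[2] + b[4])
  }, numeric(4)))
}

prepare_image <- function(model, record) {
  img <- normalize_image(record$image, model$config$pixel_mean,
                         model$config$pixel_std)
  d <- dim(img)
  H32 <- 32 * ceiling(d[1] / 32); W32 <- 32 * ceiling(d[2] / 32)
  if (H32 != d[1] || W32 != d[2]) {
    padded <- array(0, c(H32, W32, 3))
    padded[seq_len(d[1]), seq_len(d[2]), ] <- img
    img <- padded
  }
  img
}

# anchors concatenated over levels, in flattening order
all_anchors <- function(pyramid) {
  strides <- fpn_strides()
  anc <- lapply(seq_along(pyramid), function(li) {
    f <- pyramid[[li]]
    level_anchors(dim(f)[1], dim(f)[2], strides[li])
  })
  list(boxes = do.call(rbind, anc),
       counts = vapply(anc, nrow, numeric(1)))
}

# RPN target assignment: positives at IoU >= 0.7 plus the best anchor per
# gt; negatives below 0.3; sample a balanced subset
rpn_targets <- function(anchors, gtb, n_sample = 128L, pos_max = 64L) {
  n <- nrow(anchors)
  labels <- rep(NA_integer_, n)   # 1 pos, 0 neg, NA ignore
  gt_assign <- integer(n)
  if (nrow(gtb)) {
    iou <- box_iou_matrix(anchors, gtb)
    max_iou <- apply(iou, 1, max)
    gt_assign <- max.col(iou, ties.method = "first")
    labels[max_iou < 0.3] <- 0L
    labels[max_iou >= 0.7] <- 1L
    for (j in seq_len(nrow(gtb))) {
      best <- which.max(iou[, j])
      if (iou[best, j] > 0.1) labels[best] <- 1L
    }
  } else {
    labels[] <- 0L
  }
  pos <- which(labels == 1L)
  neg <- which(labels == 0L)
  if (length(pos) > pos_max) pos <- sample(pos, pos_max)
  n_neg <- min(length(neg), n_sample - length(pos))
  if (length(neg) > n_neg) neg <- sample(neg, n_neg)
  list(pos = pos, neg = neg, gt_assign = gt_assign)
}

# --- training step -----------------------------------------------------------

#' One training forward/backward pass on a single record
#'
#' Computes all losses (RPN, classification, dynamic-SmoothL1 regression,
#' mask ladder, semantic) and accumulates parameter gradients. The caller
#' owns zero_grad() and the optimizer step.
#'
#' @param model from [build_segmenter()].
#' @param record a scene record with pixels and instances.
#' @param dyn dynamic detector state from [dynamic_state()].
#' @param n_roi sampled ROIs for the box head.
#' @param n_mask positive ROIs forwarded through the mask head.
#' @return list(losses, dyn) where `losses` has components rpn_cls, rpn_box,
#'   cls, box, mask, semantic and total (their Eq-style grouped sum).
#' @export
train_step <- function(model, record, dyn, n_roi = 32L, n_mask = 4L) {
  cfg <- model$config
  img <- prepare_image(model, record)
  H <- dim(img)[1]; W <- dim(img)[2]
  feats <- model$submodules$backbone$forward(img)
  pyr <- model$submodules$fpn$forward(feats)
  grad_pyr <- lapply(pyr, function(p) array(0, dim(p)))
  gtb <- gt_boxes(record)

  # --- RPN forward, losses and proposals
  rpn <- model$submodules$rpn
  rpn_outs <- lapply(pyr, function(p) rpn$forward(p))
  anch <- all_anchors(pyr)
  cls_vec <- unlist(lapply(rpn_outs, function(o) flatten_rpn_cls(o$cls)))
  reg_mat <- do.call(rbind, lapply(rpn_outs, function(o) flatten_rpn_reg(o$reg)))
  tg <- rpn_targets(anch$boxes, gtb)
  sampled <- c(tg$pos, tg$neg)
  y <- c(rep(1, length(tg$pos)), rep(0, length(tg$neg)))
  bl <- bce_with_logits(cls_vec[sampled], y)
  loss_rpn_cls <- mean(bl$loss)
  dcls_vec <- numeric(length(cls_vec))
  dcls_vec[sampled] <- bl$grad / length(sampled)
  dreg_mat <- matrix(0, nrow(reg_mat), 4)
  loss_rpn_box <- 0
  if (length(tg$pos)) {
    tdel <- bbox_encode(gtb[tg$gt_assign[tg$pos], , drop = FALSE],
                        anch$boxes[tg$pos, , drop = FALSE])
    res <- reg_mat[tg$pos, , drop = FALSE] - tdel
    sl <- dynamic_smooth_l1(res, 1.0)
    loss_rpn_box <- sl$loss / length(sampled)
    dreg_mat[tg$pos, ] <- sl$grad / length(sampled)
  }
  props <- rpn_proposals(rpn_outs, pyr, W, H, pre_nms = 600L,
                         post_nms = 128L)
  # augment training proposals with the gt boxes plus jittered copies, so
  # the regression loss sees a stable positive population from the start
  jit <- NULL
  if (nrow(gtb)) {
    jit <- do.call(rbind, lapply(seq_len(nrow(gtb)), function(j) {
      b <- gtb[j, ]
      s <- c(b[3] - b[1], b[4] - b[2], b[3] - b[1], b[4] - b[2])
      t(replicate(4, {
        bb <- b + stats::rnorm(4, 0, 0.08) * s
        c(pmin(bb[1], bb[3] - 1), pmin(bb[2], bb[4] - 1),
          pmax(bb[3], bb[1] + 1), pmax(bb[4], bb[2] + 1))
      }))
    }))
    jit <- clip_boxes(jit, W, H)
  }
  pboxes <- rbind(props$boxes, gtb, jit)

  # --- stage-2 sampling with dynamic label assignment
  iou <- box_iou_matrix(pboxes, gtb)
  max_iou <- if (ncol(iou)) apply(iou, 1, max) else rep(0, nrow(pboxes))
  gt_assign <- if (ncol(iou)) max.col(iou, ties.method = "first")
               else integer(nrow(pboxes))
  la <- dynamic_label_assign(max_iou, dyn)
  dyn <- la$state
  pos <- which(la$labels)
  neg <- which(!la$labels)
  n_pos <- min(length(pos), n_roi %/% 4L)
  if (length(pos) > n_pos) pos <- pos[order(max_iou[pos],
                                            decreasing = TRUE)[seq_len(n_pos)]]
  n_neg <- min(length(neg), n_roi - length(pos))
  # hard-negative selection: keep the negatives closest to the positive
  # threshold (deterministic, low-variance alternative to random draws)
  if (length(neg) > n_neg) {
    neg <- neg[order(max_iou[neg], decreasing = TRUE)[seq_len(n_neg)]]
  }
  rois <- c(pos, neg)
  n_s <- length(rois)

  # --- box head: per-ROI forward, loss gradient, immediate backward
  loss_cls <- 0; loss_box <- 0
  all_res <- numeric(0)
  bh <- model$submodules$box_head
  for (k in seq_len(n_s)) {
    ri <- rois[k]
    is_pos <- k <= length(pos)
    ra <- roi_align(pyr, pboxes[ri, ], cfg$detector$roi_size)
    out <- bh$forward(ra$feat)
    p <- exp(out$cls - max(out$cls)); p <- p / sum(p)
    target <- if (is_pos) 2L else 1L     # [background, sheep]
    loss_cls <- loss_cls - log(max(p[target], 1e-12)) / n_s
    dcls <- p; dcls[target] <- dcls[target] - 1
    dcls <- dcls / n_s
    dreg <- numeric(4)
    if (is_pos) {
      tdel <- bbox_encode(gtb[gt_assign[ri], , drop = FALSE],
                          pboxes[ri, , drop = FALSE])
      res <- out$reg - as.vector(tdel)
      all_res <- c(all_res, res)
      sl <- dynamic_smooth_l1(res, dyn$beta)
      loss_box <- loss_box + sl$loss / n_s
      dreg <- sl$grad / n_s
    }
    droi <- bh$backward(dcls, dreg)
    grad_pyr <- ra$backward(droi, grad_pyr)
  }
  dyn <- dynamic_beta_update(dyn, all_res)

  # --- segmentation branch
  semh <- model$submodules$semantic_head
  sem <- semh$forward(pyr$P2)
  d_sem_feat <- array(0, dim(sem$features))
  d_sem_logits <- array(0, dim(sem$logits))
  sizes <- mask_stage_sizes(cfg$segmentation)
  mask_rois <- pos[seq_len(min(n_mask, length(pos)))]
  loss_mask <- 0
  mh <- model$submodules$mask_head
  if (length(mask_rois)) {
    for (ri in mask_rois) {
      box <- pboxes[ri, ]
      inst <- record$instances[[gt_assign[ri]]]
      ra14 <- roi_align(pyr, box, cfg$segmentation$initial_size)
      sem_pyr_f <- list(P2 = sem$features)
      sem_pyr_m <- list(P2 = sem$logits)
      sf <- lapply(sizes[seq_len(cfg$segmentation$n_stages)], function(s) {
        roi_align(sem_pyr_f, box, s, level = 1L)
      })
      sm <- lapply(sizes[seq_len(cfg$segmentation$n_stages)], function(s) {
        roi_align(sem_pyr_m, box, s, level = 1L)
      })
      stack <- mh$forward(ra14$feat, lapply(sf, `[[`, "feat"),
                          lapply(sm, `[[`, "feat"))
      gt_stage <- lapply(sizes, function(s) {
        rasterize_gt_in_box(inst$polygons, box, s)
      })
      rl <- refinement_losses(stack, gt_stage,
                              bar_width = cfg$segmentation$bar_width)
      loss_mask <- loss_mask + rl$total / length(mask_rois)
      dstack <- lapply(rl$grads$stack, function(g) g / length(mask_rois))
      gr <- mh$backward(dstack)
      grad_pyr <- ra14$backward(gr$droi, grad_pyr)
      for (s in seq_along(sf)) {
        tmp <- sf[[s]]$backward(gr$dsem_feat[[s]], list(P2 = d_sem_feat))
        d_sem_feat <- tmp$P2
        tmp <- sm[[s]]$backward(gr$dsem_mask[[s]], list(P2 = d_sem_logits))
        d_sem_logits <- tmp$P2
      }
    }
  }
  # semantic loss on the foreground union at P2 resolution
  p2h <- dim(pyr$P2)[1]; p2w <- dim(pyr$P2)[2]
  gt_sem <- matrix(FALSE, p2h, p2w)
  for (inst in record$instances) {
    polys <- lapply(inst$polygons, function(p) p / 4)
    gt_sem <- gt_sem | polygons_to_mask(polys, p2h, p2w)
  }
  slm <- matrix(sem$logits, p2h, p2w)
  sb <- bce_with_logits(slm, gt_sem * 1)
  loss_sem <- mean(sb$loss)
  d_sem_logits <- d_sem_logits + array(sb$grad / length(slm),
                                       dim(d_sem_logits))
  grad_pyr$P2 <- grad_pyr$P2 + semh$backward(d_sem_feat, d_sem_logits)

  # --- RPN backward (recompute per-level forward to restore layer caches)
  off <- 0L
  for (li in seq_along(pyr)) {
    n_l <- anch$counts[li]
    d <- dim(rpn_outs[[li]]$cls)
    npos <- d[1] * d[2]
    dcls_map <- array(dcls_vec[off + seq_len(n_l)], d)
    dreg_map <- array(0, dim(rpn_outs[[li]]$reg))
    seg <- dreg_mat[off + seq_len(n_l), , drop = FALSE]
    A <- d[3]
    for (a in seq_len(A)) {
      for (kk in 1:4) {
        dreg_map[, , (a - 1) * 4 + kk] <-
          matrix(seg[(a - 1) * npos + seq_len(npos), kk], d[1], d[2])
      }
    }
    rpn$forward(pyr[[li]])
    grad_pyr[[li]] <- grad_pyr[[li]] + rpn$backward(dcls_map, dreg_map)
    off <- off + n_l
  }

  dstages <- model$submodules$fpn$backward(grad_pyr)
  model$submodules$backbone$backward(dstages)

  losses <- list(rpn_cls = loss_rpn_cls, rpn_box = loss_rpn_box,
                 cls = loss_cls, box = loss_box, mask = loss_mask,
                 semantic = loss_sem)
  losses$total <- multi_task_loss(loss_rpn_cls + loss_cls,
                                  loss_rpn_box + loss_box,
                                  loss_mask + loss_sem)
  list(losses = losses, dyn = dyn)
}

# --- inference ---------------------------------------------------------------

#' Run inference on one scene
#'
#' Proposals from the RPN are refined by the box head (softmax score,
#' per-class deltas), filtered by score, deduplicated with NMS, and the
#' surviving detections receive 112 x 112 masks from the refinement ladder,
#' pasted into the image canvas at probability threshold 0.5.
#'
#' @param model from [build_segmenter()].
#' @param record scene record with pixels.
#' @param max_det detections kept per image.
#' @return list of detections: each list(image_id, score, box, mask).
#' @export
predict_scene <- function(model, record, max_det = 20L) {
  cfg <- model$config
  img <- prepare_image(model, record)
  H <- dim(img)[1]; W <- dim(img)[2]
  feats <- model$submodules$backbone$forward(img)
  pyr <- model$submodules$fpn$forward(feats)
  rpn_outs <- lapply(pyr, function(p) model$submodules$rpn$forward(p))
  props <- rpn_proposals(rpn_outs, pyr, W, H, pre_nms = 600L, post_nms = 100L)
  if (!nrow(props$boxes)) return(list())
  bh <- model$submodules$box_head
  scores <- numeric(nrow(props$boxes))
  boxes <- matrix(0, nrow(props$boxes), 4)
  for (i in seq_len(nrow(props$boxes))) {
    ra <- roi_align(pyr, props$boxes[i, ], cfg$detector$roi_size)
    out <- bh$forward(ra$feat)
    p <- exp(out$cls - max(out$cls)); p <- p / sum(p)
    scores[i] <- p[2]
    boxes[i, ] <- bbox_decode(matrix(out$reg, 1, 4),
                              props$boxes[i, , drop = FALSE])
  }
  boxes <- clip_boxes(boxes, record$width, record$height)
  ok <- which(scores >= cfg$detector$score_thr &
              (boxes[, 3] - boxes[, 1]) > 1 & (boxes[, 4] - boxes[, 2]) > 1)
  if (!length(ok)) return(list())
  keep <- ok[nms(boxes[ok, , drop = FALSE], scores[ok], cfg$detector$nms_iou)]
  keep <- keep[seq_len(min(max_det, length(keep)))]
  sem <- model$submodules$semantic_head$forward(pyr$P2)
  sizes <- mask_stage_sizes(cfg$segmentation)
  out <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    box <- boxes[i, ]
    ra14 <- roi_align(pyr, box, cfg$segmentation$initial_size)
    sf <- lapply(sizes[seq_len(cfg$segmentation$n_stages)], function(s) {
      roi_align(list(P2 = sem$features), box, s, level = 1L)$feat
    })
    sm <- lapply(sizes[seq_len(cfg$segmentation$n_stages)], function(s) {
      roi_align(list(P2 = sem$logits), box, s, level = 1L)$feat
    })
    stack <- model$submodules$mask_head$forward(ra14$feat, sf, sm)
    final <- stack[[length(stack)]]
    prob <- sigmoid(matrix(final, dim(final)[1], dim(final)[2]))
    mask <- paste_mask(prob, box, record$height, record$width)
    out[[j]] <- list(image_id = record$image_id, score = scores[i],
                     box = box, mask = mask)
  }
  out
}

# resize a probability tile into the detection box on the full canvas
paste_mask <- function(prob, box, H, W, thr = 0.5) {
  x1 <- max(0L, floor(box[1])); y1 <- max(0L, floor(box[2]))
  x2 <- min(W, ceiling(box[3])); y2 <- min(H, ceiling(box[4]))
  mask <- matrix(FALSE, H, W)
  bw <- x2 - x1; bh <- y2 - y1
  if (bw < 1 || bh < 1) return(mask)
  rp <- EBImage::imageData(EBImage::resize(EBImage::Image(prob),
                                           w = bh, h = bw))
  mask[(y1 + 1):y2, (x1 + 1):x2] <- rp >= thr
  mask
}
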