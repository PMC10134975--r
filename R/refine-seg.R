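# Segmentation branch: a semantic head on the highest-resolution pyramid
# level, a spatial-attention module in both heads, semantic fusion at each
# refinement stage, and a mask ladder that doubles 14 -> 28 -> 56 -> 112.
# Losses: full binary cross-entropy on the first stage and the semantic
# head; boundary-restricted cross-entropy (BAR) from the second stage on.

#' Segmentation configuration
#'
#' @param sam_kernel SAM convolution size, 3 or 7 (default 7).
#' @param sam_enabled include SAM modules (FALSE reproduces the plain
#'   refinement baseline with weights identically 1).
#' @param channels working width of the heads.
#' @param initial_size mask side after ROIAlign (14); three refinement
#'   stages double it to 112.
#' @param bar_width boundary band half-width in pixels at each stage scale.
#' @param n_stages number of refinement stages (3).
#' @return a `segmentation_config` list.
#' @export
segmentation_config <- function(sam_kernel = 7L, sam_enabled = TRUE,
                                channels = 256L, initial_size = 14L,
                                bar_width = 2L, n_stages = 3L) {
  stopifnot(sam_kernel %in% c(3L, 7L))
  structure(list(sam_kernel = as.integer(sam_kernel),
                 sam_enabled = sam_enabled, channels = as.integer(channels),
                 initial_size = as.integer(initial_size),
                 bar_width = as.integer(bar_width),
                 n_stages = as.integer(n_stages)),
            class = "segmentation_config")
}

#' Mask side at each ladder stage
#' @param config a [segmentation_config()].
#' @return integer vector, e.g. c(14, 28, 56, 112).
#' @export
mask_stage_sizes <- function(config = segmentation_config()) {
  config$initial_size * 2L^(0:config$n_stages)
}

# --- semantic head -----------------------------------------------------------

#' Build the semantic head
#'
#' Four 3x3 convolutions at the working width (no downsampling), spatial
#' attention, then a 1x1 binary classifier for the foreground probability at
#' the P2 resolution. Returns post-attention features and mask logits.
#'
#' @param config a [segmentation_config()].
#' @return an `fs_module` with `$forward(P2)` -> list(features, logits) and
#'   `$backward(dfeat, dlogits)` -> gradient for P2.
#' @export
build_semantic_head <- function(config) {
  cw <- config$channels
  sub <- list()
  for (i in 1:4) {
    sub[[paste0("conv", i)]] <- layer_conv2d(cw, cw, 3L, pad = 1L, init = "he")
    sub[[paste0("act", i)]] <- layer_relu()
  }
  if (config$sam_enabled) sub$sam <- layer_sam(config$sam_kernel)
  sub$cls <- layer_conv2d(cw, 1L, 1L, init = "0.01")
  m <- fs_module("semantic_head", submodules = sub)
  m$forward <- function(p2) {
    x <- p2
    for (i in 1:4) {
      x <- sub[[paste0("act", i)]]$forward(sub[[paste0("conv", i)]]$forward(x))
    }
    if (config$sam_enabled) x <- sub$sam$forward(x)
    list(features = x, logits = sub$cls$forward(x))
  }
  m$backward <- function(dfeat, dlogits) {
    dx <- sub$cls$backward(dlogits)
    if (!is.null(dfeat)) dx <- dx + dfeat
    if (config$sam_enabled) dx <- sub$sam$backward(dx)
    for (i in 4:1) {
      dx <- sub[[paste0("conv", i)]]$backward(
        sub[[paste0("act", i)]]$backward(dx))
    }
    dx
  }
  m
}

# --- semantic fusion ---------------------------------------------------------

#' Build a semantic fusion module (one refinement stage)
#'
#' Concatenates instance features, instance mask logits, ROI-cropped
#' semantic features and semantic mask logits along channels and projects
#' back to the working width with a 1x1 convolution and ReLU.
#'
#' @param channels working width.
#' @return an `fs_module`; `$forward(inst_feat, inst_mask, sem_feat,
#'   sem_mask)` -> fused S x S x channels array.
#' @export
build_sfm <- function(channels) {
  in_ch <- 2L * channels + 2L
  sub <- list(proj = layer_conv2d(in_ch, channels, 1L, init = "he"),
              act = layer_relu())
  m <- fs_module("sfm", submodules = sub)
  m$channels <- channels
  m$forward <- function(inst_feat, inst_mask, sem_feat, sem_mask) {
    dims <- list(dim(inst_feat)[1:2], dim(inst_mask)[1:2],
                 dim(sem_feat)[1:2], dim(sem_mask)[1:2])
    if (!all(vapply(dims, function(d) all(d == dims[[1]]), logical(1)))) {
      stop("sfm_fuse inputs must share a spatial size")
    }
    s <- dims[[1]]
    x <- array(c(inst_feat, inst_mask, sem_feat, sem_mask),
               c(s[1], s[2], in_ch))
    sub$act$forward(sub$proj$forward(x))
  }
  m$backward <- function(dy) {
    dx <- sub$proj$backward(sub$act$backward(dy))
    C <- m$channels
    list(inst_feat = dx[, , seq_len(C), drop = FALSE],
         inst_mask = dx[, , C + 1L, drop = FALSE],
         sem_feat = dx[, , C + 1L + seq_len(C), drop = FALSE],
         sem_mask = dx[, , 2L * C + 2L, drop = FALSE])
  }
  m
}

#' Fuse instance and semantic inputs (functional form)
#'
#' @param sfm module from [build_sfm()].
#' @param instance_feats,semantic_feats_roi S x S x C arrays.
#' @param instance_mask,semantic_mask_roi S x S (x 1) mask logits.
#' @return fused S x S x C array.
#' @export
sfm_fuse <- function(sfm, instance_feats, instance_mask, semantic_feats_roi,
                     semantic_mask_roi) {
  as1 <- function(x) if (length(dim(x)) == 2) array(x, c(dim(x), 1)) else x
  sfm$forward(instance_feats, as1(instance_mask), semantic_feats_roi,
              as1(semantic_mask_roi))
}

# --- mask head ---------------------------------------------------------------

#' Build the instance mask head
#'
#' Two 3x3 convolutions, spatial attention, an initial mask at the ROI size,
#' then `n_stages` refinement stages; each fuses the ROI-cropped semantic
#' output at the current size, upsamples 2x, convolves and predicts mask
#' logits, doubling 14 -> 28 -> 56 -> 112.
#'
#' @param config a [segmentation_config()].
#' @return an `fs_module`; see `$forward(roi14, sem_feat_rois,
#'   sem_mask_rois)` which returns the full logit ladder.
#' @export
build_mask_head <- function(config) {
  cw <- config$channels
  sub <- list(
    conv1 = layer_conv2d(cw, cw, 3L, pad = 1L, init = "he"),
    act1 = layer_relu(),
    conv2 = layer_conv2d(cw, cw, 3L, pad = 1L, init = "he"),
    act2 = layer_relu())
  if (config$sam_enabled) sub$sam <- layer_sam(config$sam_kernel)
  sub$mask0 <- layer_conv2d(cw, 1L, 1L, init = "0.01")
  for (s in seq_len(config$n_stages)) {
    sub[[paste0("sfm", s)]] <- build_sfm(cw)
    sub[[paste0("up", s)]] <- layer_upsample2x()
    sub[[paste0("rconv", s)]] <- layer_conv2d(cw, cw, 3L, pad = 1L,
                                              init = "he")
    sub[[paste0("ract", s)]] <- layer_relu()
    sub[[paste0("mask", s)]] <- layer_conv2d(cw, 1L, 1L, init = "0.01")
  }
  m <- fs_module("mask_head", submodules = sub)
  m$config <- config
  # sem_feat_rois / sem_mask_rois: lists indexed by stage (sizes 14, 28, 56)
  m$forward <- function(roi14, sem_feat_rois, sem_mask_rois) {
    x <- sub$act1$forward(sub$conv1$forward(roi14))
    x <- sub$act2$forward(sub$conv2$forward(x))
    if (config$sam_enabled) x <- sub$sam$forward(x)
    logits <- list(sub$mask0$forward(x))
    for (s in seq_len(config$n_stages)) {
      fused <- sub[[paste0("sfm", s)]]$forward(
        x, logits[[s]], sem_feat_rois[[s]], sem_mask_rois[[s]])
      u <- sub[[paste0("up", s)]]$forward(fused)
      x <- sub[[paste0("ract", s)]]$forward(
        sub[[paste0("rconv", s)]]$forward(u))
      logits[[s + 1]] <- sub[[paste0("mask", s)]]$forward(x)
    }
    logits
  }
  # dlogits: list of gradients per ladder entry (same shapes as logits)
  m$backward <- function(dlogits) {
    ns <- config$n_stages
    dx <- NULL
    dsem_feat <- vector("list", ns)
    dsem_mask <- vector("list", ns)
    dmask_carry <- vector("list", ns + 1)
    for (s in ns:1) {
      dl <- dlogits[[s + 1]]
      if (!is.null(dmask_carry[[s + 1]])) dl <- dl + dmask_carry[[s + 1]]
      dstage_x <- sub[[paste0("mask", s)]]$backward(dl)
      if (!is.null(dx)) dstage_x <- dstage_x + dx
      du <- sub[[paste0("rconv", s)]]$backward(
        sub[[paste0("ract", s)]]$backward(dstage_x))
      dfused <- sub[[paste0("up", s)]]$backward(du)
      parts <- sub[[paste0("sfm", s)]]$backward(dfused)
      dsem_feat[[s]] <- parts$sem_feat
      dsem_mask[[s]] <- parts$sem_mask
      dmask_carry[[s]] <- parts$inst_mask
      dx <- parts$inst_feat
    }
    # gradient reaching the trunk feature x14: from stage 1 fusion plus the
    # initial mask predictor
    dl0 <- dlogits[[1]]
    if (!is.null(dmask_carry[[1]])) dl0 <- dl0 + dmask_carry[[1]]
    dtrunk <- sub$mask0$backward(dl0) + dx
    if (config$sam_enabled) dtrunk <- sub$sam$backward(dtrunk)
    dtrunk <- sub$conv2$backward(sub$act2$backward(dtrunk))
    droi <- sub$conv1$backward(sub$act1$backward(dtrunk))
    list(droi = droi, dsem_feat = dsem_feat, dsem_mask = dsem_mask)
  }
  m
}

# --- losses ------------------------------------------------------------------

# numerically stable BCE-with-logits; returns per-pixel loss and dloss/dlogit
bce_with_logits <- function(logits, targets) {
  loss <- pmax(logits, 0) - logits * targets + log1p(exp(-abs(logits)))
  grad <- sigmoid(logits) - targets
  list(loss = loss, grad = grad)
}

#' Refinement losses over the mask ladder
#'
#' Stage 1 (the initial mask) uses mean binary cross-entropy over all
#' pixels. Later stages restrict the cross-entropy to the union of the
#' predicted and ground-truth boundary regions at that stage's scale
#' (boundary-aware refinement). The semantic head adds a mean BCE at P2
#' resolution. The total is an equally weighted sum.
#'
#' @param stack list of logit arrays at sizes 14, 28, 56, 112 (one instance).
#' @param gt_masks list of logical matrices at the same sizes.
#' @param semantic_logits H/4 x W/4 (x1) semantic logits, or NULL.
#' @param gt_semantic logical matrix at P2 resolution, or NULL.
#' @param bar_width boundary band width in pixels.
#' @return list(total, components, grads) where `grads` mirrors `stack` (and
#'   `grads$semantic` the semantic logits) with d total / d logit.
#' @export
refinement_losses <- function(stack, gt_masks, semantic_logits = NULL,
                              gt_semantic = NULL, bar_width = 2L) {
  comps <- numeric(0)
  grads <- vector("list", length(stack))
  for (s in seq_along(stack)) {
    lg <- matrix(stack[[s]], dim(stack[[s]])[1], dim(stack[[s]])[2])
    gt <- gt_masks[[s]] * 1
    bl <- bce_with_logits(lg, gt)
    if (s == 1) {
      comps <- c(comps, mean(bl$loss))
      g <- bl$grad / length(lg)
    } else {
      region <- boundary_region(gt_masks[[s]], bar_width) |
        boundary_region(matrix(sigmoid(lg) > 0.5, nrow(lg), ncol(lg)),
                        bar_width)
      if (!any(region)) {
        comps <- c(comps, 0)
        g <- lg * 0
      } else {
        comps <- c(comps, sum(bl$loss[region]) / sum(region))
        g <- bl$grad * region / sum(region)
      }
    }
    grads[[s]] <- array(g, dim(stack[[s]]))
  }
  names(comps) <- paste0("stage", seq_along(stack))
  out_grads <- list(stack = grads)
  if (!is.null(semantic_logits)) {
    sl <- semantic_logits
    d <- dim(sl)
    slm <- matrix(sl, d[1], d[2])
    bl <- bce_with_logits(slm, gt_semantic * 1)
    comps <- c(comps, semantic = mean(bl$loss))
    out_grads$semantic <- array(bl$grad / length(slm), d)
  }
  list(total = sum(comps), components = comps, grads = out_grads)
}

# ground-truth mask rasterized inside a box at a given stage resolution
rasterize_gt_in_box <- function(polygons, box, size) {
  bw <- max(box[3] - box[1], 1e-6); bh <- max(box[4] - box[2], 1e-6)
  polys <- lapply(polygons, function(p) {
    cbind(x = (p[, 1] - box[1]) / bw * size,
          y = (p[, 2] - box[2]) / bh * size)
  })
  polys <- lapply(polys, function(p) {
    cbind(x = pmin(pmax(p[, 1], 0), size), y = pmin(pmax(p[, 2], 0), size))
  })
  polygons_to_mask(polys, size, size)
}
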