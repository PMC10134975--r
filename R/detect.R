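# Detection branch: anchor-based RPN over the pyramid, bilinear ROIAlign,
# the shared box head (four layouts), dynamic label assignment and the
# dynamic SmoothL1 regression loss.

#' Detector configuration
#'
#' @param head_layout one of "2fc", "2conv+1fc", "2conv+2fc", "4conv+1fc".
#' @param roi_size ROIAlign output side for the box head (7).
#' @param roi_channels pyramid channel count feeding the head.
#' @param fc_width fully connected width (1024 in the full model).
#' @param conv_width shared conv width (equal to roi_channels).
#' @param iou_init initial IoU threshold for label assignment (0.4).
#' @param label_update_interval,label_topk dynamic-assignment bookkeeping
#'   (cited defaults: every 100 iterations, top-75).
#' @param beta_init,beta_update_interval dynamic SmoothL1 settings.
#' @param nms_iou,score_thr test-time NMS IoU and score floor.
#' @return a `detector_config` list.
#' @export
detector_config <- function(head_layout = c("2conv+1fc", "2fc", "2conv+2fc",
                                            "4conv+1fc"),
                            roi_size = 7L, roi_channels = 256L,
                            fc_width = 1024L, conv_width = roi_channels,
                            iou_init = 0.4, label_update_interval = 100L,
                            label_topk = 75L, beta_init = 1.0,
                            beta_update_interval = 100L,
                            nms_iou = 0.5, score_thr = 0.05) {
  head_layout <- match.arg(head_layout)
  stopifnot(iou_init > 0, iou_init < 1, roi_size > 0)
  structure(list(head_layout = head_layout, roi_size = as.integer(roi_size),
                 roi_channels = as.integer(roi_channels),
                 fc_width = as.integer(fc_width),
                 conv_width = as.integer(conv_width), iou_init = iou_init,
                 label_update_interval = as.integer(label_update_interval),
                 label_topk = as.integer(label_topk), beta_init = beta_init,
                 beta_update_interval = as.integer(beta_update_interval),
                 nms_iou = nms_iou, score_thr = score_thr),
            class = "detector_config")
}

# --- anchors and box coding --------------------------------------------------

# anchors for one level: 3 aspect ratios, 1 scale (base size = 8 * stride)
level_anchors <- function(h, w, stride, ratios = c(0.5, 1, 2),
                          scale = 8) {
  base <- scale * stride
  ws <- base * sqrt(1 / ratios)
  hs <- base * sqrt(ratios)
  cx <- (rep(seq_len(w), each = h) - 0.5) * stride
  cy <- (rep(seq_len(h), times = w) - 0.5) * stride
  out <- vector("list", length(ratios))
  for (a in seq_along(ratios)) {
    out[[a]] <- cbind(cx - ws[a] / 2, cy - hs[a] / 2,
                      cx + ws[a] / 2, cy + hs[a] / 2)
  }
  # order: position fastest (rows), then anchor index
  do.call(rbind, out)
}

#' Encode boxes as regression deltas relative to anchors
#' @param boxes,anchors n x 4 matrices (x1, y1, x2, y2).
#' @return n x 4 matrix of (dx, dy, dw, dh).
#' @export
bbox_encode <- function(boxes, anchors) {
  aw <- anchors[, 3] - anchors[, 1]; ah <- anchors[, 4] - anchors[, 2]
  ax <- anchors[, 1] + aw / 2; ay <- anchors[, 2] + ah / 2
  bw <- boxes[, 3] - boxes[, 1]; bh <- boxes[, 4] - boxes[, 2]
  bx <- boxes[, 1] + bw / 2; by <- boxes[, 2] + bh / 2
  cbind((bx - ax) / aw, (by - ay) / ah, log(bw / aw), log(bh / ah))
}

#' Decode regression deltas into boxes
#' @param deltas,anchors n x 4 matrices.
#' @return n x 4 box matrix.
#' @export
bbox_decode <- function(deltas, anchors) {
  aw <- anchors[, 3] - anchors[, 1]; ah <- anchors[, 4] - anchors[, 2]
  ax <- anchors[, 1] + aw / 2; ay <- anchors[, 2] + ah / 2
  lim <- log(1000 / 16)
  dw <- pmin(deltas[, 3], lim); dh <- pmin(deltas[, 4], lim)
  cx <- ax + deltas[, 1] * aw; cy <- ay + deltas[, 2] * ah
  w <- aw * exp(dw); h <- ah * exp(dh)
  cbind(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
}

clip_boxes <- function(boxes, width, height) {
  boxes[, c(1, 3)] <- pmin(pmax(boxes[, c(1, 3)], 0), width)
  boxes[, c(2, 4)] <- pmin(pmax(boxes[, c(2, 4)], 0), height)
  boxes
}

# IoU matrix between two box sets
box_iou_matrix <- function(a, b) {
  n <- nrow(a); m <- nrow(b)
  out <- matrix(0, n, m)
  if (n == 0 || m == 0) return(out)
  area_a <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2])
  area_b <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
  for (j in seq_len(m)) {
    ix <- pmax(0, pmin(a[, 3], b[j, 3]) - pmax(a[, 1], b[j, 1]))
    iy <- pmax(0, pmin(a[, 4], b[j, 4]) - pmax(a[, 2], b[j, 2]))
    inter <- ix * iy
    out[, j] <- inter / pmax(area_a + area_b[j] - inter, 1e-10)
  }
  out
}

#' Greedy non-maximum suppression
#' @param boxes n x 4 matrix; `scores` length-n.
#' @param iou_thr suppression threshold.
#' @return indices of kept boxes, score-descending.
#' @export
nms <- function(boxes, scores, iou_thr = 0.7) {
  ord <- order(scores, decreasing = TRUE)
  keep <- integer(0)
  while (length(ord)) {
    i <- ord[1]
    keep <- c(keep, i)
    if (length(ord) == 1) break
    rest <- ord[-1]
    ious <- box_iou_matrix(boxes[rest, , drop = FALSE],
                           boxes[i, , drop = FALSE])[, 1]
    ord <- rest[ious <= iou_thr]
  }
  keep
}

# --- RPN ---------------------------------------------------------------------

build_rpn <- function(channels, n_anchors = 3L) {
  sub <- list(
    conv = layer_conv2d(channels, channels, 3L, pad = 1L, init = "he"),
    act = layer_relu(),
    cls = layer_conv2d(channels, n_anchors, 1L, init = "0.01"),
    reg = layer_conv2d(channels, 4L * n_anchors, 1L, init = "0.01"))
  m <- fs_module("rpn", submodules = sub)
  m$n_anchors <- n_anchors
  m$forward <- function(level_feat) {
    h <- sub$act$forward(sub$conv$forward(level_feat))
    list(cls = sub$cls$forward(h), reg = sub$reg$forward(h))
  }
  m$backward <- function(dcls, dreg) {
    dh <- sub$cls$backward(dcls) + sub$reg$backward(dreg)
    sub$conv$backward(sub$act$backward(dh))
  }
  m
}

# flatten per-level RPN maps to per-anchor vectors matching level_anchors order
flatten_rpn_cls <- function(cls_map) as.vector(cls_map)
flatten_rpn_reg <- function(reg_map) {
  d <- dim(reg_map)
  npos <- d[1] * d[2]
  A <- d[3] / 4
  out <- matrix(0, npos * A, 4)
  for (a in seq_len(A)) {
    for (k in 1:4) {
      out[(a - 1) * npos + seq_len(npos), k] <- reg_map[, , (a - 1) * 4 + k]
    }
  }
  out
}

#' Decode RPN outputs into scored proposals
#'
#' @param rpn_outs per-level list of `list(cls, reg)` maps.
#' @param pyramid the feature pyramid (for level sizes).
#' @param img_w,img_h image size for clipping.
#' @param pre_nms,post_nms kept proposal counts before/after NMS.
#' @param nms_thr NMS IoU threshold (0.7).
#' @return list(boxes = n x 4, scores, levels).
#' @export
rpn_proposals <- function(rpn_outs, pyramid, img_w, img_h,
                          pre_nms = 1000L, post_nms = 1000L, nms_thr = 0.7) {
  strides <- fpn_strides()
  all_boxes <- NULL; all_scores <- NULL; all_levels <- NULL
  for (li in seq_along(pyramid)) {
    f <- pyramid[[li]]
    anc <- level_anchors(dim(f)[1], dim(f)[2], strides[li])
    sc <- sigmoid(flatten_rpn_cls(rpn_outs[[li]]$cls))
    dl <- flatten_rpn_reg(rpn_outs[[li]]$reg)
    keep <- order(sc, decreasing = TRUE)[seq_len(min(pre_nms, length(sc)))]
    bx <- clip_boxes(bbox_decode(dl[keep, , drop = FALSE],
                                 anc[keep, , drop = FALSE]), img_w, img_h)
    ok <- (bx[, 3] - bx[, 1]) > 1e-3 & (bx[, 4] - bx[, 2]) > 1e-3
    all_boxes <- rbind(all_boxes, bx[ok, , drop = FALSE])
    all_scores <- c(all_scores, sc[keep][ok])
    all_levels <- c(all_levels, rep(li, sum(ok)))
  }
  if (is.null(all_boxes) || nrow(all_boxes) == 0) {
    return(list(boxes = matrix(0, 0, 4), scores = numeric(0),
                levels = integer(0)))
  }
  kp <- nms(all_boxes, all_scores, nms_thr)
  kp <- kp[seq_len(min(post_nms, length(kp)))]
  list(boxes = all_boxes[kp, , drop = FALSE], scores = all_scores[kp],
       levels = all_levels[kp])
}

# --- ROIAlign ----------------------------------------------------------------

# standard FPN level assignment for an ROI (levels P2..P5 -> indices 1..4)
roi_level <- function(box) {
  s <- sqrt(max(box[3] - box[1], 1e-6) * max(box[4] - box[2], 1e-6))
  min(max(floor(4 + log2(s / 224 + 1e-8)), 2), 5) - 1
}

#' Bilinear ROIAlign from a feature pyramid
#'
#' One sample point per output bin, taken at the bin center and bilinearly
#' interpolated from the assigned pyramid level (chosen by the standard
#' scale rule). Returns the sampled feature and a closure that scatters a
#' gradient back into a pyramid-gradient accumulator.
#'
#' @param pyramid named list P2..P6.
#' @param box (x1, y1, x2, y2) in image coordinates.
#' @param output_size output side (7 for the box head, 14 for the mask head).
#' @param level optional fixed level index (1..4 for P2..P5).
#' @return list(feat = S x S x C array, backward = function(dy, grad_pyr)).
#' @export
roi_align <- function(pyramid, box, output_size = 7L, level = NULL) {
  if (is.null(level)) level <- roi_level(box)
  lev_name <- names(fpn_strides())[level]
  stride <- fpn_strides()[[level]]
  f <- pyramid[[lev_name]]
  d <- dim(f)
  C <- d[3]
  S <- output_size
  bw <- box[3] - box[1]; bh <- box[4] - box[2]
  if (bw <= 1e-3 || bh <= 1e-3) {
    warning("degenerate box in roi_align; returning zeros")
    zero <- array(0, c(S, S, C))
    return(list(feat = zero, backward = function(dy, grad_pyr) grad_pyr,
                level = lev_name))
  }
  # bin-center sample points in feature coordinates (aligned convention)
  xs <- box[1] + (seq_len(S) - 0.5) * bw / S
  ys <- box[2] + (seq_len(S) - 0.5) * bh / S
  fx <- xs / stride - 0.5
  fy <- ys / stride - 0.5
  fx <- pmin(pmax(fx, 0), d[2] - 1)
  fy <- pmin(pmax(fy, 0), d[1] - 1)
  x0 <- pmin(floor(fx), d[2] - 1); x1 <- pmin(x0 + 1, d[2] - 1)
  y0 <- pmin(floor(fy), d[1] - 1); y1 <- pmin(y0 + 1, d[1] - 1)
  wx <- fx - x0; wy <- fy - y0
  # grids: rows = S*S sample points (y fastest), 4 corners
  gy0 <- rep(y0, times = S); gy1 <- rep(y1, times = S)
  gwy <- rep(wy, times = S)
  gx0 <- rep(x0, each = S); gx1 <- rep(x1, each = S)
  gwx <- rep(wx, each = S)
  fm <- matrix(f, d[1] * d[2], C)
  i00 <- gy0 + gx0 * d[1] + 1; i01 <- gy0 + gx1 * d[1] + 1
  i10 <- gy1 + gx0 * d[1] + 1; i11 <- gy1 + gx1 * d[1] + 1
  w00 <- (1 - gwy) * (1 - gwx); w01 <- (1 - gwy) * gwx
  w10 <- gwy * (1 - gwx); w11 <- gwy * gwx
  feat <- fm[i00, , drop = FALSE] * w00 + fm[i01, , drop = FALSE] * w01 +
    fm[i10, , drop = FALSE] * w10 + fm[i11, , drop = FALSE] * w11
  bwd <- function(dy, grad_pyr) {
    dym <- matrix(dy, S * S, C)
    g <- matrix(grad_pyr[[lev_name]], d[1] * d[2], C)
    for (set in list(list(i00, w00), list(i01, w01),
                     list(i10, w10), list(i11, w11))) {
      contrib <- dym * set[[2]]
      agg <- rowsum(contrib, group = set[[1]])
      rows <- as.integer(rownames(agg))
      g[rows, ] <- g[rows, ] + agg
    }
    grad_pyr[[lev_name]] <- array(g, d)
    grad_pyr
  }
  list(feat = array(feat, c(S, S, C)), backward = bwd, level = lev_name)
}

# --- box head ----------------------------------------------------------------

head_layouts <- c("2fc", "2conv+1fc", "2conv+2fc", "4conv+1fc")

#' Build the second-stage box head
#'
#' Shared trunk per layout (convs are 3x3, padding 1, width `conv_width`;
#' FCs are `fc_width` wide), followed by parallel class logits
#' (background + sheep) and per-class box deltas.
#'
#' @param config a [detector_config()].
#' @param n_classes foreground class count (1).
#' @return an `fs_module` with `$forward(roi)` -> list(cls, reg) and
#'   `$backward(dcls, dreg)` -> gradient for the ROI feature.
#' @export
build_box_head <- function(config, n_classes = 1L) {
  layout <- config$head_layout
  if (!layout %in% head_layouts) stop("unknown head layout: ", layout)
  cw <- config$conv_width; fw <- config$fc_width; S <- config$roi_size
  n_conv <- switch(layout, "2fc" = 0L, "2conv+1fc" = 2L, "2conv+2fc" = 2L,
                   "4conv+1fc" = 4L)
  n_fc <- switch(layout, "2fc" = 2L, "2conv+1fc" = 1L, "2conv+2fc" = 2L,
                 "4conv+1fc" = 1L)
  sub <- list()
  for (i in seq_len(n_conv)) {
    sub[[paste0("conv", i)]] <- layer_conv2d(cw, cw, 3L, pad = 1L, init = "he")
    sub[[paste0("cact", i)]] <- layer_relu()
  }
  flat_dim <- cw * S * S
  for (i in seq_len(n_fc)) {
    sub[[paste0("fc", i)]] <- layer_linear(if (i == 1) flat_dim else fw, fw)
    sub[[paste0("fact", i)]] <- layer_relu()
  }
  sub$cls <- layer_linear(fw, n_classes + 1L, init = "0.01")
  sub$reg <- layer_linear(fw, 4L * n_classes, init = "0.001")
  m <- fs_module("box_head", submodules = sub)
  m$layout <- layout
  m$forward <- function(roi) {
    x <- roi
    for (i in seq_len(n_conv)) {
      x <- sub[[paste0("cact", i)]]$forward(sub[[paste0("conv", i)]]$forward(x))
    }
    m$flat_dim_in <- dim(x)
    x <- as.vector(x)
    for (i in seq_len(n_fc)) {
      x <- sub[[paste0("fact", i)]]$forward(sub[[paste0("fc", i)]]$forward(x))
    }
    list(cls = sub$cls$forward(x), reg = sub$reg$forward(x))
  }
  m$backward <- function(dcls, dreg) {
    dx <- sub$cls$backward(dcls) + sub$reg$backward(dreg)
    for (i in rev(seq_len(n_fc))) {
      dx <- sub[[paste0("fc", i)]]$backward(sub[[paste0("fact", i)]]$backward(dx))
    }
    dx <- array(dx, m$flat_dim_in)
    for (i in rev(seq_len(n_conv))) {
      dx <- sub[[paste0("conv", i)]]$backward(
        sub[[paste0("cact", i)]]$backward(dx))
    }
    dx
  }
  m
}

#' Closed-form parameter delta of a head layout vs the 2-FC baseline
#'
#' Counts only the shared trunk (the parallel predictors are identical across
#' layouts). With the full-model widths (256-channel 7x7 ROI, width-1024
#' FCs) the deltas are +130,560, +1,180,160 and +1,310,720 for
#' "2conv+1fc", "2conv+2fc" and "4conv+1fc".
#'
#' @param layout one of the four layouts.
#' @param roi_channels,roi_size,fc_width head dimensions.
#' @return integer-valued parameter difference.
#' @export
head_parameter_delta <- function(layout, roi_channels = 256L, roi_size = 7L,
                                 fc_width = 1024L) {
  if (!layout %in% head_layouts) stop("unknown head layout: ", layout)
  conv_p <- 9 * roi_channels * roi_channels + roi_channels
  flat <- roi_channels * roi_size * roi_size
  fc1 <- flat * fc_width + fc_width
  fc2 <- fc_width * fc_width + fc_width
  trunk <- function(lay) {
    switch(lay,
           "2fc" = fc1 + fc2,
           "2conv+1fc" = 2 * conv_p + fc1,
           "2conv+2fc" = 2 * conv_p + fc1 + fc2,
           "4conv+1fc" = 4 * conv_p + fc1)
  }
  trunk(layout) - trunk("2fc")
}

# --- dynamic training strategies --------------------------------------------

#' Fresh dynamic-assignment / dynamic-beta state
#' @param config a [detector_config()].
#' @return a state list used by [dynamic_label_assign()] and
#'   [dynamic_beta_update()].
#' @export
dynamic_state <- function(config) {
  list(threshold = config$iou_init, iou_init = config$iou_init,
       topk = config$label_topk, interval = config$label_update_interval,
       iou_record = numeric(0), beta = config$beta_init,
       beta_init = config$beta_init,
       beta_interval = config$beta_update_interval,
       beta_record = numeric(0), iter = 0L)
}

#' Dynamic label assignment
#'
#' Proposals with IoU at or above the current threshold are positive. The
#' state records the top-K proposal IoU of each image; every
#' `update_interval` iterations the threshold moves to the mean of the
#' recorded values (never below its initial 0.4), tracking the improving
#' proposal quality during training.
#'
#' @param proposal_ious per-proposal max IoU against ground truth (one image).
#' @param state from [dynamic_state()].
#' @return list(labels = logical vector, state = updated state).
#' @export
dynamic_label_assign <- function(proposal_ious, state) {
  labels <- if (length(proposal_ious)) proposal_ious >= state$threshold
            else logical(0)
  if (length(proposal_ious)) {
    k <- min(state$topk, length(proposal_ious))
    kth <- sort(proposal_ious, decreasing = TRUE)[k]
    state$iou_record <- c(state$iou_record, kth)
  }
  state$iter <- state$iter + 1L
  if (state$iter %% state$interval == 0L && length(state$iou_record)) {
    state$threshold <- max(state$iou_init, mean(state$iou_record))
    state$iou_record <- numeric(0)
  }
  list(labels = labels, state = state)
}

#' Dynamic SmoothL1 loss
#'
#' Per coordinate: `0.5 r^2 / beta` for `|r| < beta`, else `|r| - 0.5 beta`;
#' summed. Shrinking `beta` sharpens the quadratic zone, increasing the
#' gradient on small residuals as regression targets concentrate.
#'
#' @param residual numeric vector/matrix of regression residuals.
#' @param beta positive shape parameter.
#' @return list(loss = scalar, grad = d loss / d residual).
#' @export
dynamic_smooth_l1 <- function(residual, beta) {
  if (beta <= 0) stop("beta must be positive")
  a <- abs(residual)
  quad <- a < beta
  loss <- sum(ifelse(quad, 0.5 * residual^2 / beta, a - 0.5 * beta))
  grad <- ifelse(quad, residual / beta, sign(residual))
  list(loss = loss, grad = grad)
}

#' Record residuals and periodically shrink beta
#'
#' Keeps the median of recent regression residual magnitudes; every
#' `beta_update_interval` iterations beta becomes that median, clipped to at
#' most `beta_init`.
#'
#' @param state from [dynamic_state()].
#' @param residuals positive-label regression residuals of this iteration.
#' @return updated state.
#' @export
dynamic_beta_update <- function(state, residuals) {
  if (length(residuals)) {
    state$beta_record <- c(state$beta_record, stats::median(abs(residuals)))
  }
  if (state$iter %% state$beta_interval == 0L && length(state$beta_record)) {
    state$beta <- min(state$beta_init,
                      max(stats::median(state$beta_record), 1e-3))
    state$beta_record <- numeric(0)
  }
  state
}
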