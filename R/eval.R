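# COCO-style average precision for boxes and masks, plus Boundary IoU /
# Boundary AP. Single category; AP averages IoU thresholds 0.50:0.05:0.95
# with 101-point precision-recall interpolation.

#' Precision and recall from match counts
#'
#' @param tp,fp,fn non-negative counts.
#' @return named numeric `(precision, recall)`; 0/0 is defined as 0.
#' @export
precision_recall <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) stop("counts must be non-negative")
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  c(precision = p, recall = r)
}

#' Mask intersection-over-union
#'
#' @param A,B logical matrices on the same canvas.
#' @return IoU in [0, 1]; 0 if both masks are empty.
#' @export
mask_iou <- function(A, B) {
  if (!all(dim(A) == dim(B))) stop("masks must share a canvas")
  u <- sum(A | B)
  if (u == 0) return(0)
  sum(A & B) / u
}

#' Box intersection-over-union
#' @param a,b boxes as (x1, y1, x2, y2).
#' @return IoU in [0, 1].
#' @export
box_iou <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  ua <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  if (ua <= 0) return(0)
  inter / ua
}

#' Boundary IoU of two masks
#'
#' IoU of the contour bands: for each mask, the set of its pixels within
#' Euclidean distance `d` of its contour (the canvas border counts as
#' contour). Objects thin enough to lie entirely within `d` of their contour
#' reduce to plain mask IoU.
#'
#' @param B_gt,P logical masks on the same canvas.
#' @param d band width in pixels (>= 1); see [boundary_width()].
#' @return Boundary IoU in [0, 1]; 0 if both bands are empty.
#' @export
boundary_iou <- function(B_gt, P, d) {
  if (!all(dim(B_gt) == dim(P))) stop("masks must share a canvas")
  if (d < 1) stop("d must be >= 1")
  bb <- boundary_band(B_gt, d)
  pb <- boundary_band(P, d)
  u <- sum(bb | pb)
  if (u == 0) return(0)
  sum(bb & pb) / u
}

#' Boundary band width from the image size
#'
#' 2% of the image diagonal, rounded, floored at 1 pixel (1920 x 1080 gives
#' 44 px).
#'
#' @param image_w,image_h image size in pixels.
#' @return integer width in pixels.
#' @export
boundary_width <- function(image_w, image_h) {
  max(1L, as.integer(round(0.02 * sqrt(image_w^2 + image_h^2))))
}

#' COCO-style average precision
#'
#' Detections are matched greedily per image in global score-descending
#' order: each detection takes the unmatched ground truth with the highest
#' IoU at or above the threshold. Per threshold, precision is interpolated
#' onto 101 recall points; AP is the mean over thresholds 0.50:0.05:0.95.
#'
#' @param detections list of lists with fields `image_id`, `score`, `obj`
#'   (a mask or box, whatever `iou_fn` consumes).
#' @param gts list of lists with fields `image_id`, `obj`.
#' @param iou_fn function(det_obj, gt_obj) -> IoU.
#' @param thresholds IoU threshold ladder.
#' @return named numeric with `AP`, `AP50`, `AP75`; carries attribute
#'   `degenerate = TRUE` when there are no ground truths.
#' @export
average_precision <- function(detections, gts, iou_fn,
                              thresholds = seq(0.5, 0.95, by = 0.05)) {
  n_gt <- length(gts)
  if (n_gt == 0) {
    out <- c(AP = 0, AP50 = 0, AP75 = 0)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  scores <- vapply(detections, function(d) d$score, numeric(1))
  ord <- order(scores, decreasing = TRUE)
  gt_img <- vapply(gts, function(g) g$image_id, numeric(1))
  # IoU of each detection against the ground truths of its image (computed once)
  iou_rows <- lapply(ord, function(i) {
    gsel <- which(gt_img == detections[[i]]$image_id)
    list(gsel = gsel,
         iou = vapply(gsel, function(j) iou_fn(detections[[i]]$obj,
                                               gts[[j]]$obj), numeric(1)))
  })
  rec_pts <- seq(0, 1, by = 0.01)
  ap_t <- numeric(length(thresholds))
  for (ti in seq_along(thresholds)) {
    thr <- thresholds[ti]
    gt_used <- logical(n_gt)
    tp <- integer(length(ord)); fp <- integer(length(ord))
    for (k in seq_along(ord)) {
      row <- iou_rows[[k]]
      best <- 0; best_j <- 0L
      for (m in seq_along(row$gsel)) {
        j <- row$gsel[m]
        if (!gt_used[j] && row$iou[m] >= thr && row$iou[m] > best) {
          best <- row$iou[m]; best_j <- j
        }
      }
      if (best_j > 0L) { tp[k] <- 1L; gt_used[best_j] <- TRUE } else fp[k] <- 1L
    }
    ctp <- cumsum(tp); cfp <- cumsum(fp)
    recall <- ctp / n_gt
    precision <- ifelse(ctp + cfp == 0, 0, ctp / (ctp + cfp))
    # precision envelope, then sample at the 101 recall points
    if (length(precision)) {
      for (k in rev(seq_along(precision))[-1]) {
        precision[k] <- max(precision[k], precision[k + 1])
      }
    }
    q <- numeric(length(rec_pts))
    if (length(recall)) {
      pos <- findInterval(rec_pts, recall, left.open = TRUE) + 1
      ok <- pos <= length(precision)
      q[ok] <- precision[pos[ok]]
    }
    ap_t[ti] <- mean(q)
  }
  names(ap_t) <- sprintf("%.2f", thresholds)
  pick <- function(nm) if (nm %in% names(ap_t)) ap_t[[nm]] else NA_real_
  c(AP = mean(ap_t), AP50 = pick("0.50"), AP75 = pick("0.75"))
}

#' Evaluate detections against ground truth across metric families
#'
#' @param pred list of predictions: each a list with `image_id`, `score`,
#'   `box` (x1,y1,x2,y2) and `mask` (logical matrix on the image canvas).
#' @param records ground-truth scene records.
#' @param families subset of c("box", "mask", "boundary").
#' @return data.frame with one row per family and columns AP, AP50, AP75
#'   (fractions in [0, 1]).
#' @export
eval_report <- function(pred, records,
                        families = c("box", "mask", "boundary")) {
  gts_mask <- list(); gts_box <- list()
  d_by_img <- list()
  for (r in records) {
    d_by_img[[as.character(r$image_id)]] <- boundary_width(r$width, r$height)
    for (inst in r$instances) {
      m <- polygons_to_mask(inst$polygons, r$height, r$width)
      bb <- inst$bbox
      gts_mask[[length(gts_mask) + 1]] <- list(image_id = r$image_id, obj = m)
      gts_box[[length(gts_box) + 1]] <- list(
        image_id = r$image_id, obj = c(bb[1], bb[2], bb[1] + bb[3], bb[2] + bb[4]))
    }
  }
  rows <- list()
  for (fam in families) {
    res <- switch(fam,
      box = average_precision(
        lapply(pred, function(p) list(image_id = p$image_id, score = p$score,
                                      obj = p$box)),
        gts_box, function(a, b) box_iou(a, b)),
      mask = average_precision(
        lapply(pred, function(p) list(image_id = p$image_id, score = p$score,
                                      obj = p$mask)),
        gts_mask, mask_iou),
      boundary = {
        pb <- lapply(pred, function(p) {
          d <- d_by_img[[as.character(p$image_id)]]
          list(image_id = p$image_id, score = p$score,
               obj = boundary_band(p$mask, d))
        })
        gb <- lapply(gts_mask, function(g) {
          d <- d_by_img[[as.character(g$image_id)]]
          list(image_id = g$image_id, obj = boundary_band(g$obj, d))
        })
        average_precision(pb, gb, mask_iou)
      })
    rows[[fam]] <- data.frame(family = fam, AP = res[["AP"]],
                              AP50 = res[["AP50"]], AP75 = res[["AP75"]])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
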