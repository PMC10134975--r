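# Independent brute-force oracles used across the suite. These deliberately
# re-derive results through different algorithms than the package
# (point-by-point scans, quadratic loops, direct formula evaluation) so that
# agreement is evidence, not tautology.

# even-odd point-in-polygon by explicit crossing count for a single point
oracle_point_in_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  crossings <- 0
  for (e in seq_len(n)) {
    x1 <- poly[e, 1]; y1 <- poly[e, 2]
    x2 <- poly[if (e == n) 1 else e + 1, 1]
    y2 <- poly[if (e == n) 1 else e + 1, 2]
    if ((y1 <= y && y < y2) || (y2 <= y && y < y1)) {
      xi <- x1 + (y - y1) * (x2 - x1) / (y2 - y1)
      if (x < xi) crossings <- crossings + 1
    }
  }
  crossings %% 2 == 1
}

# full-canvas rasterization oracle (pixel centers, union over polygons)
oracle_rasterize <- function(polygons, height, width) {
  if (is.matrix(polygons)) polygons <- list(polygons)
  m <- matrix(FALSE, height, width)
  for (r in seq_len(height)) {
    for (c in seq_len(width)) {
      for (p in polygons) {
        if (oracle_point_in_polygon(c - 0.5, r - 0.5, p)) {
          m[r, c] <- TRUE
          break
        }
      }
    }
  }
  m
}

# exact Euclidean distance from each pixel to the nearest pixel of `set`
# (quadratic scan); border = TRUE adds a virtual background ring
oracle_distance_to <- function(set, border = FALSE) {
  H <- nrow(set); W <- ncol(set)
  pts <- which(set, arr.ind = TRUE)
  if (border) {
    ring <- rbind(cbind(0, 0:(W + 1)), cbind(H + 1, 0:(W + 1)),
                  cbind(0:(H + 1), 0), cbind(0:(H + 1), W + 1))
    pts <- rbind(pts, ring)
  }
  out <- matrix(Inf, H, W)
  if (!nrow(pts)) return(out)
  for (r in seq_len(H)) {
    for (c in seq_len(W)) {
      out[r, c] <- sqrt(min((pts[, 1] - r)^2 + (pts[, 2] - c)^2))
    }
  }
  out
}

# one-sided contour band oracle: mask pixels within d of background
oracle_boundary_band <- function(mask, d) {
  mask & (oracle_distance_to(!mask, border = TRUE) <= d)
}

# two-sided boundary region oracle
oracle_boundary_region <- function(mask, w) {
  inner <- mask & (oracle_distance_to(!mask, border = TRUE) <= w)
  outer <- (!mask) & (oracle_distance_to(mask) <= w)
  inner | outer
}

# pixel-loop mask IoU
oracle_mask_iou <- function(A, B) {
  inter <- 0; uni <- 0
  for (i in seq_along(A)) {
    if (A[i] && B[i]) inter <- inter + 1
    if (A[i] || B[i]) uni <- uni + 1
  }
  if (uni == 0) 0 else inter / uni
}

# three-line ECA oracle: pool -> padded 1-D correlation -> sigmoid
oracle_eca_weights <- function(X, w) {
  z <- apply(X, 3, mean)
  k <- length(w); h <- (k - 1) / 2
  zp <- c(numeric(h), z, numeric(h))
  s <- vapply(seq_along(z), function(i) sum(w * zp[i:(i + k - 1)]), numeric(1))
  1 / (1 + exp(-s))
}

# direct SAM oracle: mean/max maps -> k x k correlation -> sigmoid
oracle_sam_weights <- function(X, kernel) {
  H <- dim(X)[1]; W <- dim(X)[2]
  k <- dim(kernel)[1]; h <- (k - 1) / 2
  avg <- apply(X, c(1, 2), mean)
  mx <- apply(X, c(1, 2), max)
  padA <- matrix(0, H + 2 * h, W + 2 * h)
  padM <- padA
  padA[h + seq_len(H), h + seq_len(W)] <- avg
  padM[h + seq_len(H), h + seq_len(W)] <- mx
  out <- matrix(0, H, W)
  for (r in seq_len(H)) {
    for (c in seq_len(W)) {
      acc <- 0
      for (dr in seq_len(k)) {
        for (dc in seq_len(k)) {
          acc <- acc + kernel[dr, dc, 1] * padA[r + dr - 1, c + dc - 1] +
            kernel[dr, dc, 2] * padM[r + dr - 1, c + dc - 1]
        }
      }
      out[r, c] <- 1 / (1 + exp(-acc))
    }
  }
  out
}

# independent COCO-style AP evaluator: explicit per-threshold PR table and
# the 101-point rule, coded separately from the package's evaluator
oracle_average_precision <- function(detections, gts, iou_fn,
                                     thresholds = seq(0.5, 0.95, 0.05)) {
  n_gt <- length(gts)
  scores <- sapply(detections, function(d) d$score)
  ord <- order(-scores)
  aps <- c()
  for (thr in thresholds) {
    used <- rep(FALSE, n_gt)
    flags <- c()
    for (i in ord) {
      det <- detections[[i]]
      best_iou <- -1; best_j <- 0
      for (j in seq_len(n_gt)) {
        if (used[j]) next
        if (gts[[j]]$image_id != det$image_id) next
        v <- iou_fn(det$obj, gts[[j]]$obj)
        if (v >= thr && v > best_iou) { best_iou <- v; best_j <- j }
      }
      if (best_j > 0) { used[best_j] <- TRUE; flags <- c(flags, 1) }
      else flags <- c(flags, 0)
    }
    tp <- cumsum(flags); fp <- cumsum(1 - flags)
    rec <- tp / n_gt
    prec <- tp / pmax(tp + fp, 1)
    # monotone envelope
    for (i in rev(seq_along(prec))[-1]) prec[i] <- max(prec[i], prec[i + 1])
    q <- numeric(101)
    rts <- seq(0, 1, 0.01)
    for (m in seq_along(rts)) {
      hit <- which(rec >= rts[m])
      q[m] <- if (length(hit)) prec[hit[1]] else 0
    }
    aps <- c(aps, mean(q))
  }
  names(aps) <- sprintf("%.2f", thresholds)
  aps
}

# small deterministic random mask
random_mask <- function(h, w, p = 0.4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::runif(h * w) < p, h, w)
}

# a tiny two-image COCO fixture built in code (continuous coordinates)
make_coco_fixture <- function(dir) {
  r1 <- new_scene_record(1, 32, 32, NULL, list(
    new_instance(1, list(cbind(x = c(4, 12.5, 12.5, 4), y = c(4, 4, 10.25, 10.25))),
                 c(4, 4, 8.5, 6.25), 48),
    new_instance(1, list(cbind(x = c(16, 28, 22), y = c(16, 16, 28))),
                 c(16, 16, 12, 12), 66)))
  r2 <- new_scene_record(2, 32, 32, NULL, list(
    new_instance(1, list(cbind(x = c(2, 30, 30, 2), y = c(20, 20, 30, 30))),
                 c(2, 20, 28, 10), 280)))
  path <- file.path(dir, "fixture.json")
  write_coco(list(r1, r2), path)
  path
}
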