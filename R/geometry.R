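# Polygon/mask geometry. Masks are logical H x W matrices; a pixel at row r,
# column c (1-based) has center (c - 0.5, r - 0.5) in continuous 0-based
# image coordinates, so pixel membership is decided by center containment
# with the even-odd rule. mask_to_polygons() traces the exact rectilinear
# pixel boundary, so polygons_to_mask(mask_to_polygons(m)) == m identically.

#' Rasterize polygons to a binary mask
#'
#' A pixel is set iff its center lies inside any polygon under the even-odd
#' rule; the mask is the union over polygons. Vertices outside the canvas
#' (beyond a small tolerance) are clamped with a warning.
#'
#' @param polygons a single n x 2 matrix (columns x, y) or a list of them;
#'   vertices in continuous pixel coordinates, polygon implicitly closed.
#' @param height,width canvas size in pixels.
#' @return logical `height` x `width` matrix.
#' @export
polygons_to_mask <- function(polygons, height, width) {
  if (is.matrix(polygons)) polygons <- list(polygons)
  mask <- matrix(FALSE, height, width)
  for (poly in polygons) {
    if (is.null(dim(poly))) poly <- matrix(poly, ncol = 2, byrow = TRUE)
    if (nrow(poly) < 3) next
    tol <- 1e-6
    if (any(poly[, 1] < -tol | poly[, 1] > width + tol |
            poly[, 2] < -tol | poly[, 2] > height + tol)) {
      warning("polygon vertex outside canvas; clamping")
    }
    px <- pmin(pmax(poly[, 1], 0), width)
    py <- pmin(pmax(poly[, 2], 0), height)
    mask <- mask | rasterize_even_odd(px, py, height, width)
  }
  mask
}

# crossing-parity rasterization of one closed polygon
rasterize_even_odd <- function(px, py, height, width) {
  n <- length(px)
  x2 <- c(px[-1], px[1])
  y2 <- c(py[-1], py[1])
  plus_rows <- integer(0)                 # +1 event at column 1
  minus_lin <- integer(0)                 # -1 event at linear index (row, col)
  for (e in seq_len(n)) {
    ya <- py[e]; yb <- y2[e]
    if (ya == yb) next
    ylo <- min(ya, yb); yhi <- max(ya, yb)
    r0 <- max(ceiling(ylo - 0.5), 0)       # first row with center >= ylo
    r1 <- min(ceiling(yhi - 0.5) - 1, height - 1)  # last row with center < yhi
    if (r0 > r1) next
    rows <- r0:r1
    yc <- rows + 0.5
    xi <- px[e] + (yc - ya) * (x2[e] - px[e]) / (yb - ya)
    # pixel centers with xc = c + 0.5 < xi  =>  columns 0 .. cnt - 1
    cnt <- pmin(pmax(ceiling(xi - 0.5), 0), width)
    keep <- cnt > 0
    if (any(keep)) {
      ri <- rows[keep] + 1L
      plus_rows <- c(plus_rows, ri)
      ci <- cnt[keep] + 1L
      inb <- ci <= width
      if (any(inb)) minus_lin <- c(minus_lin, ri[inb] + (ci[inb] - 1L) * height)
    }
  }
  nev <- height * (width + 1L)
  ev <- tabulate(plus_rows, nbins = nev) - tabulate(minus_lin, nbins = nev)
  events <- matrix(ev, height, width + 1L)
  counts <- t(apply(events, 1, cumsum))[, seq_len(width), drop = FALSE]
  counts %% 2L == 1L
}

#' Tight bounding box of a binary mask
#'
#' @param mask logical matrix.
#' @return numeric `(x, y, w, h)` in 0-based pixel coordinates (COCO
#'   convention: the box spans `[x, x + w) x [y, y + h)`).
#' @export
mask_to_bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    stop(structure(class = c("flockseg_empty_mask", "error", "condition"),
                   list(message = "empty mask has no bounding box",
                        call = sys.call(-1))))
  }
  r <- range(idx[, 1]); c <- range(idx[, 2])
  c(x = c[1] - 1, y = r[1] - 1, w = c[2] - c[1] + 1, h = r[2] - r[1] + 1)
}

#' Trace a binary mask into exact boundary polygons
#'
#' Produces one vertex list (integer corner coordinates) tracing the
#' rectilinear boundary of the pixel set. Multiple loops (separate components
#' or holes) are joined by doubled zero-width bridges so that even-odd
#' rasterization of the single polygon reproduces the mask exactly.
#'
#' @param mask logical matrix.
#' @return list with one n x 2 matrix (columns x, y), or an empty list for an
#'   empty mask.
#' @export
mask_to_polygons <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(list())
  r <- idx[, 1]; c <- idx[, 2]
  pad <- matrix(FALSE, H + 2, W + 2)
  pad[cbind(r + 1L, c + 1L)] <- TRUE
  # directed boundary edges, interior on the right; corner (x, y) with
  # x in 0..W, y in 0..H; direction codes 0:+x 1:+y 2:-x 3:-y
  ex <- integer(0); ey <- integer(0); ed <- integer(0)
  up <- !pad[cbind(r, c + 1L)]
  dn <- !pad[cbind(r + 2L, c + 1L)]
  lf <- !pad[cbind(r + 1L, c)]
  rt <- !pad[cbind(r + 1L, c + 2L)]
  ex <- c(c[up] - 1L, c[rt], c[dn], c[lf] - 1L)
  ey <- c(r[up] - 1L, r[rt] - 1L, r[dn], r[lf])
  ed <- c(rep(0L, sum(up)), rep(1L, sum(rt)),
          rep(2L, sum(dn)), rep(3L, sum(lf)))
  ne <- length(ex)
  key <- ex + ey * (W + 1L)
  # up to two outgoing edges per corner
  ord <- order(key)
  ex <- ex[ord]; ey <- ey[ord]; ed <- ed[ord]; key <- key[ord]
  first <- match(unique(key), key)
  slot <- new.env(parent = emptyenv())
  for (i in seq_along(first)) {
    k <- key[first[i]]
    n2 <- if (i < length(first)) first[i + 1] - first[i] else ne - first[i] + 1
    assign(as.character(k), first[i]:(first[i] + n2 - 1), envir = slot)
  }
  used <- logical(ne)
  dxs <- c(1L, 0L, -1L, 0L)
  dys <- c(0L, 1L, 0L, -1L)
  loops <- list()
  for (start in seq_len(ne)) {
    if (used[start]) next
    verts_x <- integer(0); verts_y <- integer(0)
    cur <- start
    repeat {
      used[cur] <- TRUE
      verts_x <- c(verts_x, ex[cur]); verts_y <- c(verts_y, ey[cur])
      nx <- ex[cur] + dxs[ed[cur] + 1L]
      ny <- ey[cur] + dys[ed[cur] + 1L]
      if (nx == ex[start] && ny == ey[start] && length(verts_x) > 1) break
      cand <- get0(as.character(nx + ny * (W + 1L)), envir = slot)
      cand <- cand[!used[cand]]
      if (length(cand) == 0) {
        if (nx == ex[start] && ny == ey[start]) break
        stop("boundary tracing failed (internal error)")
      }
      if (length(cand) > 1) {
        # pinch corner: turn toward the interior (right turn) to keep loops tight
        pref <- (ed[cur] + 1L) %% 4L
        hit <- cand[ed[cand] == pref]
        cur <- if (length(hit)) hit[1] else cand[1]
      } else {
        cur <- cand
      }
    }
    # merge collinear runs
    n <- length(verts_x)
    if (n > 2) {
      keep <- logical(n)
      for (i in seq_len(n)) {
        p <- if (i == 1) n else i - 1
        nn <- if (i == n) 1 else i + 1
        keep[i] <- (verts_x[p] - verts_x[i]) * (verts_y[i] - verts_y[nn]) !=
                   (verts_y[p] - verts_y[i]) * (verts_x[i] - verts_x[nn])
      }
      verts_x <- verts_x[keep]; verts_y <- verts_y[keep]
    }
    loops[[length(loops) + 1]] <- cbind(x = verts_x, y = verts_y)
  }
  if (length(loops) == 1) return(list(loops[[1]]))
  # join loops with doubled bridges through the first loop's first vertex
  anchor <- loops[[1]][1, , drop = FALSE]
  out <- rbind(loops[[1]], anchor)
  for (i in 2:length(loops)) {
    out <- rbind(out, loops[[i]], loops[[i]][1, , drop = FALSE], anchor)
  }
  list(out)
}

#' Polygon area of the union of an instance's polygons (by rasterization)
#' @keywords internal
polygons_area <- function(polygons, height, width) {
  sum(polygons_to_mask(polygons, height, width))
}

# Exact Euclidean distance (in pixels) from every pixel to the nearest
# background (FALSE) pixel; the canvas border counts as background.
dist_to_background <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(0, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- mask * 1
  dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(pad),
                                            metric = "euclidean"))
  dm[2:(H + 1), 2:(W + 1), drop = FALSE]
}

#' Band of mask pixels near the contour (one-sided)
#'
#' Mask pixels whose Euclidean distance to the nearest background pixel is at
#' most `d`; the canvas border counts as background. This is the `X_d`
#' intersect `X` set used by Boundary IoU.
#'
#' @param mask logical matrix.
#' @param d band width in pixels.
#' @return logical matrix, a subset of `mask`.
#' @export
boundary_band <- function(mask, d) {
  if (!any(mask)) return(mask & FALSE)
  mask & (dist_to_background(mask) <= d)
}

#' Two-sided boundary region around a mask contour
#'
#' All pixels (inside or outside the mask) within Euclidean distance
#' `width_px` of the mask/background interface. Used by the boundary-aware
#' refinement loss.
#'
#' @param mask logical matrix.
#' @param width_px band half-width in pixels (>= 1).
#' @return logical matrix; empty if the mask is empty.
#' @export
boundary_region <- function(mask, width_px) {
  if (width_px < 1) stop("width_px must be >= 1")
  if (!any(mask)) return(mask & FALSE)
  inner <- mask & (dist_to_background(mask) <= width_px)
  if (all(mask)) {
    outer_band <- mask & FALSE
  } else {
    outer_band <- (!mask) & (dist_to_foreground(mask) <= width_px)
  }
  inner | outer_band
}

# distance from every pixel to the nearest foreground (TRUE) pixel
dist_to_foreground <- function(mask) {
  dm <- EBImage::imageData(EBImage::distmap(EBImage::Image((!mask) * 1),
                                            metric = "euclidean"))
  matrix(dm, nrow(mask), ncol(mask))
}
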