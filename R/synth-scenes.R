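# Synthetic scenes of overlapping, irregular-contour instances. The farm
# imagery this emulates is not public; these scenes reproduce its two hard
# properties -- wavy instance boundaries and heavy pairwise overlap -- with
# exact, programmatically known ground truth.

#' Blob specification
#'
#' @param center length-2 numeric (x, y) in pixels.
#' @param base_radius mean contour radius in pixels (> 0).
#' @param n_harmonics number of radial harmonics perturbing the contour.
#' @param amplitude total relative radial perturbation in [0, 1).
#' @param texture_seed integer seed fixing harmonics, phases and texture.
#' @return a `blob_spec` list.
#' @export
blob_spec <- function(center, base_radius, n_harmonics = 5, amplitude = 0.25,
                      texture_seed = 0L) {
  stopifnot(base_radius > 0, amplitude >= 0, amplitude < 1)
  structure(list(center = as.numeric(center), base_radius = base_radius,
                 n_harmonics = as.integer(n_harmonics),
                 amplitude = amplitude, texture_seed = as.integer(texture_seed)),
            class = "blob_spec")
}

#' Sample an irregular closed contour
#'
#' Vertex k sits at angle `theta_k = 2*pi*k/n` with radius
#' `base_radius * (1 + amplitude * sum_h a_h sin(h*theta_k + phi_h))`, the
#' harmonic amplitudes `a_h` (normalized so their absolute sum is 1) and
#' phases drawn deterministically from `texture_seed`. Because the
#' perturbation is bounded by `amplitude < 1`, every radius is positive and
#' the contour never crosses the center.
#'
#' @param spec a [blob_spec()].
#' @param n_vertices number of contour vertices (>= 8).
#' @return an `n_vertices` x 2 matrix (columns x, y).
#' @export
sample_blob_polygon <- function(spec, n_vertices = 64L) {
  if (n_vertices < 8) stop("n_vertices must be >= 8")
  th <- 2 * pi * (seq_len(n_vertices) - 1) / n_vertices
  r <- rep(spec$base_radius, n_vertices)
  if (spec$amplitude > 0 && spec$n_harmonics > 0) {
    hp <- with_seed(spec$texture_seed, {
      a <- stats::runif(spec$n_harmonics, 0.3, 1) / seq_len(spec$n_harmonics)
      list(a = a / sum(abs(a)), phi = stats::runif(spec$n_harmonics, 0, 2 * pi))
    })
    pert <- rep(0, n_vertices)
    for (h in seq_len(spec$n_harmonics)) {
      pert <- pert + hp$a[h] * sin(h * th + hp$phi[h])
    }
    r <- spec$base_radius * (1 + spec$amplitude * pert)
    if (any(r <= 0)) {
      # unreachable with normalized harmonics; guard per contract
      message("non-positive radius; regenerating with halved amplitude")
      spec$amplitude <- spec$amplitude / 2
      return(sample_blob_polygon(spec, n_vertices))
    }
  }
  cbind(x = spec$center[1] + r * cos(th), y = spec$center[2] + r * sin(th))
}

#' Scene specification
#'
#' @param width,height canvas size in pixels.
#' @param n_instances number of blobs to place (>= 0).
#' @param overlap_target desired mean pairwise mask IoU in [0, 1).
#' @param background_style one of "flat", "gradient", "noise".
#' @param illumination_gain multiplicative brightness factor.
#' @param seed integer seed; the scene is deterministic in it.
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(width = 256L, height = 256L, n_instances = 3L,
                       overlap_target = 0.1,
                       background_style = c("flat", "gradient", "noise"),
                       illumination_gain = 1, seed = 0L) {
  stopifnot(n_instances >= 0, overlap_target >= 0, overlap_target < 1)
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_instances = as.integer(n_instances),
                 overlap_target = overlap_target,
                 background_style = match.arg(background_style),
                 illumination_gain = illumination_gain,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# distance between two equal circles of radius R at which area-IoU == target
circle_iou_distance <- function(R, target) {
  if (target <= 0) return(3.5 * R)
  f <- function(d) {
    if (d >= 2 * R) return(-target)
    inter <- 2 * R^2 * acos(d / (2 * R)) - d / 2 * sqrt(4 * R^2 - d^2)
    inter / (2 * pi * R^2 - inter) - target
  }
  stats::uniroot(f, c(1e-6, 2 * R - 1e-6))$root
}

#' Compose a synthetic scene
#'
#' Blobs are drawn back-to-front; each annotation describes only the visible
#' (unoccluded) part of its instance, matching polygon tracing of what is
#' seen. Fully occluded instances are dropped. Boxes, areas and polygons are
#' recomputed from the visible mask, so every annotation re-rasterizes to its
#' mask exactly.
#'
#' @param spec a [scene_spec()].
#' @return a scene record with pixels and exact annotations; the achieved
#'   mean pairwise IoU of the full (pre-occlusion) masks is attached as the
#'   `achieved_overlap` attribute.
#' @export
compose_scene <- function(spec) {
  with_seed(spec$seed, compose_scene_impl(spec))
}

compose_scene_impl <- function(spec) {
  W <- spec$width; H <- spec$height
  img <- scene_background(spec)
  n <- spec$n_instances
  if (n == 0) {
    rec <- new_scene_record(spec$seed, W, H, img)
    attr(rec, "achieved_overlap") <- 0
    return(rec)
  }
  R <- 0.16 * min(W, H) * stats::runif(n, 0.8, 1.2)
  margin <- R * (1 + 0.35)
  centers <- matrix(0, n, 2)
  centers[1, ] <- c(stats::runif(1, margin[1], W - margin[1]),
                    stats::runif(1, margin[1], H - margin[1]))
  if (n > 1) {
    for (i in 2:n) {
      ref <- sample.int(i - 1, 1)
      d <- circle_iou_distance(mean(R[c(ref, i)]), spec$overlap_target)
      for (try in 1:20) {
        ang <- stats::runif(1, 0, 2 * pi)
        cand <- centers[ref, ] + d * c(cos(ang), sin(ang))
        if (all(cand >= margin[i] * 0.6) && cand[1] <= W - margin[i] * 0.6 &&
            cand[2] <= H - margin[i] * 0.6) break
      }
      centers[i, ] <- pmin(pmax(cand, R[i] * 0.5), c(W, H) - R[i] * 0.5)
    }
  }
  full_masks <- vector("list", n)
  polys <- vector("list", n)
  for (i in seq_len(n)) {
    bs <- blob_spec(centers[i, ], R[i], n_harmonics = 5,
                    amplitude = stats::runif(1, 0.15, 0.3),
                    texture_seed = derive_seed(spec$seed, i, 29L))
    poly <- sample_blob_polygon(bs, 64L)
    poly[, 1] <- pmin(pmax(poly[, 1], 0), W)
    poly[, 2] <- pmin(pmax(poly[, 2], 0), H)
    polys[[i]] <- poly
    full_masks[[i]] <- polygons_to_mask(poly, H, W)
  }
  achieved <- 0
  if (n > 1) {
    ious <- c()
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      ious <- c(ious, mask_iou(full_masks[[i]], full_masks[[j]]))
    }
    achieved <- mean(ious)
    if (abs(achieved - spec$overlap_target) > 0.2) {
      warning(sprintf(
        "overlap target %.2f not achieved (got %.2f); best effort",
        spec$overlap_target, achieved))
    }
  }
  # paint back-to-front and keep visible-only masks
  instances <- list()
  for (i in seq_len(n)) {
    visible <- full_masks[[i]]
    if (i < n) for (j in (i + 1):n) visible <- visible & !full_masks[[j]]
    gray <- stats::runif(1, 140, 235)
    speckle <- matrix(stats::rnorm(H * W, 0, 9), H, W)
    sel <- which(full_masks[[i]])
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[sel] <- gray + speckle[sel]
      img[, , ch] <- plane
    }
    if (!any(visible)) next
    vp <- mask_to_polygons(visible)
    instances[[length(instances) + 1]] <-
      new_instance(1L, vp, mask_to_bbox(visible), sum(visible))
  }
  img <- pmin(pmax(img * spec$illumination_gain, 0), 255)
  rec <- new_scene_record(spec$seed, W, H, img, instances)
  attr(rec, "achieved_overlap") <- achieved
  rec
}

scene_background <- function(spec) {
  H <- spec$height; W <- spec$width
  base <- switch(spec$background_style,
    flat = array(stats::runif(1, 40, 90), c(H, W, 3)),
    gradient = {
      g0 <- stats::runif(1, 30, 70); g1 <- g0 + stats::runif(1, 20, 60)
      grad <- matrix(rep(seq(g0, g1, length.out = W), each = H), H, W)
      array(rep(grad, 3), c(H, W, 3))
    },
    noise = {
      g <- matrix(stats::runif(1, 40, 90) + stats::rnorm(H * W, 0, 12), H, W)
      array(rep(g, 3), c(H, W, 3))
    })
  base
}

#' Generate a synthetic dataset
#'
#' @param n_scenes number of scenes (>= 1).
#' @param spec_fn function(i) returning the [scene_spec()] for scene i; its
#'   `seed` field is overridden by a seed derived from `seed` and `i`. The
#'   default samples canvas-256 scenes with 1..10 instances and overlap
#'   targets up to 0.3, mirroring flock imagery with varying crowding.
#' @param seed master integer seed; output is deterministic in it.
#' @param out_dir if non-NULL, writes `annotations.json` plus one PNG per
#'   scene into this directory.
#' @return list of scene records (invisibly also written to disk).
#' @export
generate_dataset <- function(n_scenes, spec_fn = NULL, seed = 0L,
                             out_dir = NULL) {
  stopifnot(n_scenes >= 1)
  if (is.null(spec_fn)) {
    spec_fn <- function(i) {
      with_seed(derive_seed(seed, i, 7L), scene_spec(
        width = 256L, height = 256L,
        n_instances = sample(1:10, 1),
        overlap_target = stats::runif(1, 0, 0.3),
        background_style = sample(c("flat", "gradient", "noise"), 1)))
    }
  }
  records <- vector("list", n_scenes)
  for (i in seq_len(n_scenes)) {
    sp <- spec_fn(i)
    sp$seed <- derive_seed(seed, i, 13L)
    rec <- suppressWarnings(compose_scene(sp))
    rec$image_id <- i
    records[[i]] <- rec
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_coco(records, file.path(out_dir, "annotations.json"))
    for (r in records) {
      write_image_png(r$image, file.path(out_dir,
                                         sprintf("scene_%06d.png", r$image_id)))
    }
  }
  records
}

# deterministic derived seed kept within 32-bit integer range
derive_seed <- function(seed, i, salt) {
  as.integer((as.numeric(seed) * 48271 + i * 69621 + salt * 1013) %% 2147483647)
}
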