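# Training-time augmentation: Copy-Paste, standard/large scale jittering,
# random horizontal flip, pad-to-square and channel normalization. Every
# transform rebuilds annotations from transformed polygons and re-derives
# exact polygons from the resulting visible masks, so augmented records
# always pass validate_scene().

#' Augmentation configuration
#'
#' @param jitter_mode "SSJ" (scale 0.8..1.25), "LSJ" (0.1..2.0) or "none".
#' @param output_size canvas side after crop/pad (default 1024).
#' @param pad_value 8-bit gray used for padding (default mid-gray 128).
#' @param flip_prob probability of a horizontal flip.
#' @param copy_paste_enabled enable Copy-Paste in the pipeline.
#' @param min_visible_area smallest pixel count for an annotation to survive
#'   occlusion or cropping (degenerate-instance guard).
#' @return an `augment_config` list.
#' @export
augment_config <- function(jitter_mode = c("LSJ", "SSJ", "none"),
                           output_size = 1024L, pad_value = 128,
                           flip_prob = 0.5, copy_paste_enabled = TRUE,
                           min_visible_area = 10) {
  jitter_mode <- match.arg(jitter_mode)
  structure(list(jitter_mode = jitter_mode,
                 ssj_range = c(0.8, 1.25), lsj_range = c(0.1, 2.0),
                 output_size = as.integer(output_size), pad_value = pad_value,
                 flip_prob = flip_prob,
                 copy_paste_enabled = copy_paste_enabled,
                 min_visible_area = min_visible_area),
            class = "augment_config")
}

# rebuild one instance from a visible mask (NULL if below the area floor)
instance_from_mask <- function(mask, category_id, min_area) {
  a <- sum(mask)
  if (a < min_area) return(NULL)
  new_instance(category_id, mask_to_polygons(mask), mask_to_bbox(mask), a)
}

#' Scale jittering with crop/pad to a square canvas
#'
#' Draws an isotropic scale from the configured range, resizes image and
#' polygons, then crops (scale > canvas) or pads (scale < canvas) to
#' `output_size` x `output_size` with `pad_value`. Instances left without
#' visible pixels are dropped.
#'
#' @param record a scene record (with pixels).
#' @param config an [augment_config()].
#' @param scale optional fixed scale overriding the random draw.
#' @return the augmented scene record.
#' @export
scale_jitter <- function(record, config, scale = NULL) {
  rng <- switch(config$jitter_mode, SSJ = config$ssj_range,
                LSJ = config$lsj_range, none = c(1, 1))
  s <- if (!is.null(scale)) scale else stats::runif(1, rng[1], rng[2])
  out_sz <- config$output_size
  nh <- max(1L, as.integer(round(record$height * s)))
  nw <- max(1L, as.integer(round(record$width * s)))
  sy <- nh / record$height
  sx <- nw / record$width
  img <- resize_bilinear(record$image, nh, nw)
  # crop anchor (random top-left within valid range) or pad at the origin
  crop_y <- if (nh > out_sz) sample.int(nh - out_sz + 1L, 1L) - 1L else 0L
  crop_x <- if (nw > out_sz) sample.int(nw - out_sz + 1L, 1L) - 1L else 0L
  canvas <- array(config$pad_value, c(out_sz, out_sz, 3))
  cy <- min(nh - crop_y, out_sz); cx <- min(nw - crop_x, out_sz)
  canvas[seq_len(cy), seq_len(cx), ] <-
    img[crop_y + seq_len(cy), crop_x + seq_len(cx), , drop = FALSE]
  instances <- list()
  for (inst in record$instances) {
    polys <- lapply(inst$polygons, function(p) {
      cbind(x = p[, 1] * sx - crop_x, y = p[, 2] * sy - crop_y)
    })
    polys <- lapply(polys, function(p) {
      cbind(x = pmin(pmax(p[, 1], 0), out_sz),
            y = pmin(pmax(p[, 2], 0), out_sz))
    })
    mask <- polygons_to_mask(polys, out_sz, out_sz)
    ni <- instance_from_mask(mask, inst$category_id, config$min_visible_area)
    if (!is.null(ni)) instances[[length(instances) + 1]] <- ni
  }
  new_scene_record(record$image_id, out_sz, out_sz, canvas, instances)
}

resize_bilinear <- function(image, nh, nw) {
  d <- dim(image)
  if (d[1] == nh && d[2] == nw) return(image)
  out <- EBImage::resize(EBImage::Image(image / 255, colormode = "Color"),
                         w = nh, h = nw)   # EBImage x = first array dim
  EBImage::imageData(out) * 255
}

#' Copy-Paste augmentation
#'
#' Composites `n_paste` donor instances at random positions onto the host.
#' Pasted pixels overwrite the host; host annotations lose pasted-over
#' pixels and are dropped when (almost) nothing remains; pasted annotations
#' are appended with exact recomputed polygons/boxes/areas.
#'
#' @param donor,host scene records with pixels.
#' @param n_paste number of instances to paste (sampled with replacement,
#'   with a message, if it exceeds the donor count).
#' @return the augmented host record.
#' @export
copy_paste <- function(donor, host, n_paste = 1L, min_visible_area = 10) {
  if (length(donor$instances) < 1) stop("donor has no instances")
  replace <- n_paste > length(donor$instances)
  if (replace) message("n_paste exceeds donor instances; sampling with replacement")
  pick <- sample.int(length(donor$instances), n_paste, replace = replace)
  H <- host$height; W <- host$width
  img <- host$image
  host_masks <- scene_masks(host)
  pasted <- list()
  for (pi in pick) {
    inst <- donor$instances[[pi]]
    dm <- polygons_to_mask(inst$polygons, donor$height, donor$width)
    bb <- mask_to_bbox(dm)
    # random placement keeping the instance box inside the host canvas
    ox <- sample.int(max(1L, W - bb["w"] + 1L), 1L) - 1L - bb["x"]
    oy <- sample.int(max(1L, H - bb["h"] + 1L), 1L) - 1L - bb["y"]
    src <- which(dm, arr.ind = TRUE)
    dst_r <- src[, 1] + oy; dst_c <- src[, 2] + ox
    ok <- dst_r >= 1 & dst_r <= H & dst_c >= 1 & dst_c <= W
    if (!any(ok)) next
    src <- src[ok, , drop = FALSE]
    dst <- cbind(dst_r[ok], dst_c[ok])
    pm <- matrix(FALSE, H, W)
    pm[dst] <- TRUE
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[dst] <- donor$image[, , ch][src]
      img[, , ch] <- plane
    }
    host_masks <- lapply(host_masks, function(m) m & !pm)
    for (j in seq_along(pasted)) pasted[[j]]$mask <- pasted[[j]]$mask & !pm
    pasted[[length(pasted) + 1]] <- list(mask = pm,
                                         category_id = inst$category_id)
  }
  instances <- list()
  for (i in seq_along(host_masks)) {
    ni <- instance_from_mask(host_masks[[i]],
                             host$instances[[i]]$category_id, min_visible_area)
    if (!is.null(ni)) instances[[length(instances) + 1]] <- ni
  }
  for (p in pasted) {
    ni <- instance_from_mask(p$mask, p$category_id, min_visible_area)
    if (!is.null(ni)) instances[[length(instances) + 1]] <- ni
  }
  new_scene_record(host$image_id, W, H, img, instances)
}

#' Random horizontal flip
#'
#' With probability `flip_prob`, mirrors the image and all annotations about
#' the vertical center line. Applying the flip twice is the identity.
#'
#' @param record a scene record.
#' @param flip_prob flip probability in [0, 1].
#' @param force NULL for a random draw, or TRUE/FALSE to force the outcome.
#' @return the (possibly) flipped record.
#' @export
random_flip <- function(record, flip_prob = 0.5, force = NULL) {
  do_flip <- if (is.null(force)) stats::runif(1) < flip_prob else force
  if (!do_flip) return(record)
  W <- record$width
  img <- record$image
  if (!is.null(img)) img <- img[, rev(seq_len(ncol(img))), , drop = FALSE]
  instances <- lapply(record$instances, function(inst) {
    polys <- lapply(inst$polygons, function(p) cbind(x = W - p[, 1], y = p[, 2]))
    bb <- inst$bbox
    new_instance(inst$category_id, polys,
                 c(W - bb[1] - bb[3], bb[2], bb[3], bb[4]), inst$area,
                 inst$iscrowd)
  })
  new_scene_record(record$image_id, W, record$height, img, instances)
}

#' Channelwise normalization
#'
#' @param image H x W x 3 array in 0..255.
#' @param mean,std per-channel statistics; `std` must be positive.
#' @return float array `(image - mean) / std`.
#' @export
normalize_image <- function(image, mean = c(123.675, 116.28, 103.53),
                            std = c(58.395, 57.12, 57.375)) {
  if (any(std <= 0)) stop("std must be positive")
  out <- image
  for (ch in 1:3) out[, , ch] <- (image[, , ch] - mean[ch]) / std[ch]
  out
}

#' Inverse of [normalize_image()]
#' @inheritParams normalize_image
#' @export
denormalize_image <- function(image, mean = c(123.675, 116.28, 103.53),
                              std = c(58.395, 57.12, 57.375)) {
  out <- image
  for (ch in 1:3) out[, , ch] <- image[, , ch] * std[ch] + mean[ch]
  out
}

#' Full augmentation pipeline
#'
#' Copy-Paste (when enabled and a donor is given), scale jitter, random flip.
#' With all augmentations disabled ("none" jitter, zero flip probability,
#' Copy-Paste off and canvas-sized output) the pipeline is the identity.
#'
#' @param record host scene record.
#' @param config an [augment_config()].
#' @param donor optional donor record for Copy-Paste.
#' @return the augmented record.
#' @export
augment_record <- function(record, config, donor = NULL) {
  if (config$copy_paste_enabled && !is.null(donor) &&
      length(donor$instances) > 0) {
    record <- copy_paste(donor, record,
                         n_paste = sample.int(min(3L, length(donor$instances)), 1L),
                         min_visible_area = config$min_visible_area)
  }
  if (config$jitter_mode != "none" || record$width != config$output_size ||
      record$height != config$output_size) {
    record <- scale_jitter(record, config)
  }
  random_flip(record, config$flip_prob)
}
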