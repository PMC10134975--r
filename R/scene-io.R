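# COCO-format dataset input/output and the train/val/test split.
#
# A scene record is a list:
#   image_id, width, height, image (H x W x 3 array in 0..255, or NULL),
#   instances = list of lists(category_id, polygons, bbox, area, iscrowd)
# Polygons are lists of n x 2 matrices (columns x, y) in continuous 0-based
# pixel coordinates; bbox is COCO (x, y, w, h).

#' Construct a scene record
#'
#' @param image_id integer id.
#' @param width,height canvas size in pixels.
#' @param image H x W x 3 array in 0..255, or NULL.
#' @param instances list of instance annotations (see [new_instance()]).
#' @return a `flockseg_scene` list.
#' @export
new_scene_record <- function(image_id, width, height, image = NULL,
                             instances = list()) {
  structure(list(image_id = as.integer(image_id), width = as.integer(width),
                 height = as.integer(height), image = image,
                 instances = instances),
            class = "flockseg_scene")
}

#' Construct an instance annotation
#'
#' @param category_id integer category (1 = sheep).
#' @param polygons list of n x 2 vertex matrices (columns x, y).
#' @param bbox COCO (x, y, w, h).
#' @param area mask area in pixels squared.
#' @param iscrowd crowd flag (0 here; crowd training is out of scope).
#' @return an instance annotation list.
#' @export
new_instance <- function(category_id, polygons, bbox, area, iscrowd = 0L) {
  list(category_id = as.integer(category_id), polygons = polygons,
       bbox = as.numeric(bbox), area = as.numeric(area),
       iscrowd = as.integer(iscrowd))
}

#' @export
print.flockseg_scene <- function(x, ...) {
  cat(sprintf("<scene %d: %dx%d, %d instance%s%s>\n", x$image_id, x$width,
              x$height, length(x$instances),
              if (length(x$instances) == 1) "" else "s",
              if (is.null(x$image)) ", no pixels" else ""))
  invisible(x)
}

#' Load a COCO-format instance segmentation dataset
#'
#' Reads an annotation JSON (with `images`, `annotations`, `categories`) and
#' groups annotations by image. Polygon segmentations are preserved verbatim;
#' uncompressed RLE segmentations are decoded to masks and re-traced to exact
#' polygons. Image pixels are loaded from PNG files under `image_root` when
#' present; missing files yield records without pixels (sufficient for
#' annotation-only workflows).
#'
#' @param annotation_file path to the COCO JSON.
#' @param image_root directory containing the image files (optional).
#' @return list of scene records, plus a `categories` attribute.
#' @export
load_coco <- function(annotation_file, image_root = NULL) {
  doc <- jsonlite::fromJSON(annotation_file, simplifyVector = FALSE)
  for (key in c("images", "annotations", "categories")) {
    if (is.null(doc[[key]])) {
      stop("not a COCO annotation file: missing key '", key, "'")
    }
  }
  img_ids <- vapply(doc$images, function(im) as.integer(im$id), integer(1))
  by_img <- vector("list", length(img_ids))
  names(by_img) <- as.character(img_ids)
  for (ann in doc$annotations) {
    k <- as.character(as.integer(ann$image_id))
    if (is.na(match(k, names(by_img)))) {
      stop("annotation ", ann$id, " references unknown image_id ",
           ann$image_id)
    }
    by_img[[k]] <- c(by_img[[k]], list(ann))
  }
  records <- vector("list", length(doc$images))
  for (i in seq_along(doc$images)) {
    im <- doc$images[[i]]
    w <- as.integer(im$width); h <- as.integer(im$height)
    pixels <- NULL
    if (!is.null(image_root) && !is.null(im$file_name)) {
      f <- file.path(image_root, im$file_name)
      if (file.exists(f)) pixels <- read_image_png(f)
    }
    anns <- by_img[[as.character(as.integer(im$id))]]
    instances <- lapply(anns, function(a) decode_annotation(a, h, w))
    records[[i]] <- new_scene_record(im$id, w, h, pixels, instances)
  }
  attr(records, "categories") <- doc$categories
  records
}

decode_annotation <- function(a, height, width) {
  seg <- a$segmentation
  if (!is.null(seg$counts)) {
    if (is.character(seg$counts)) {
      stop("compressed RLE segmentations are not supported; ",
           "use uncompressed counts or polygons")
    }
    mask <- rle_to_mask(unlist(seg$counts), unlist(seg$size))
    polygons <- mask_to_polygons(mask)
  } else {
    polygons <- lapply(seg, function(fl) {
      fl <- unlist(fl)
      matrix(fl, ncol = 2, byrow = TRUE, dimnames = list(NULL, c("x", "y")))
    })
  }
  new_instance(a$category_id, polygons, unlist(a$bbox),
               if (is.null(a$area)) NA_real_ else a$area,
               if (is.null(a$iscrowd)) 0L else a$iscrowd)
}

# COCO uncompressed RLE: column-major runs, starting with background
rle_to_mask <- function(counts, size) {
  v <- rep(rep(c(0L, 1L), length.out = length(counts)), counts)
  matrix(as.logical(v), size[1], size[2])
}

read_image_png <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2) px <- array(rep(px, 3), c(dim(px), 3))
  px[, , 1:3, drop = FALSE] * 255
}

write_image_png <- function(image, path) {
  png::writePNG(pmin(pmax(image / 255, 0), 1), path)
}

#' Write scene records as a COCO annotation file
#'
#' Annotation ids are assigned contiguously from 1. Non-crowd instances are
#' always written as polygons.
#'
#' @param records list of scene records.
#' @param path output JSON path.
#' @param categories category table; defaults to the single category "sheep".
#' @return invisibly, `path`.
#' @export
write_coco <- function(records, path,
                       categories = list(list(id = 1, name = "sheep",
                                              supercategory = "animal"))) {
  ids <- vapply(records, function(r) r$image_id, integer(1))
  if (anyDuplicated(ids)) stop("duplicate image_id in records")
  images <- lapply(records, function(r) {
    list(id = r$image_id, width = r$width, height = r$height,
         file_name = sprintf("scene_%06d.png", r$image_id))
  })
  annotations <- list()
  aid <- 0L
  for (r in records) {
    for (inst in r$instances) {
      aid <- aid + 1L
      seg <- lapply(inst$polygons, function(p) as.numeric(t(p)))
      annotations[[aid]] <- list(
        id = aid, image_id = r$image_id, category_id = inst$category_id,
        segmentation = seg, bbox = as.numeric(inst$bbox),
        area = inst$area, iscrowd = inst$iscrowd)
    }
  }
  doc <- list(images = images, annotations = annotations,
              categories = categories)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' Random 6:2:2-style dataset split
#'
#' Validation and test sizes are the nearest-integer rounding of their ratio
#' times N; the training set takes the remainder (1396 ids with ratios 6:2:2
#' give 838/279/279). Membership comes from a seeded shuffle, so the same
#' seed always yields the same split.
#'
#' @param ids vector of image ids (length >= 3).
#' @param ratios length-3 positive weights for train/val/test (normalized).
#' @param seed integer seed for the shuffle.
#' @return list with `train`, `val`, `test` id vectors.
#' @export
split_dataset <- function(ids, ratios = c(6, 2, 2), seed = 0L) {
  if (length(ratios) != 3 || any(ratios <= 0)) {
    stop("ratios must be three positive numbers")
  }
  n <- length(ids)
  if (n < 3) stop("need at least 3 ids to split")
  ratios <- ratios / sum(ratios)
  n_val <- round(ratios[2] * n)
  n_test <- round(ratios[3] * n)
  n_train <- n - n_val - n_test
  if (min(n_train, n_val, n_test) < 1) {
    stop("split produced an empty subset; adjust ratios or id count")
  }
  shuffled <- with_seed(seed, sample(ids, n))
  list(train = shuffled[seq_len(n_train)],
       val = shuffled[n_train + seq_len(n_val)],
       test = shuffled[n_train + n_val + seq_len(n_test)])
}

# run code under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Validate a scene record's annotation invariants
#'
#' Checks that every instance has a non-empty mask, that the stored bbox is
#' the tight box of the rasterized polygons, that the stored area matches the
#' mask, and that re-rasterizing the polygons reproduces a consistent mask.
#'
#' @param record a scene record.
#' @param tol bbox/area tolerance in pixels.
#' @return TRUE invisibly, or an error describing the first violation.
#' @export
validate_scene <- function(record, tol = 1.5) {
  stopifnot(record$width > 0, record$height > 0)
  for (i in seq_along(record$instances)) {
    inst <- record$instances[[i]]
    mask <- polygons_to_mask(inst$polygons, record$height, record$width)
    if (!any(mask)) stop("instance ", i, " has an empty mask")
    bb <- mask_to_bbox(mask)
    if (any(abs(bb - inst$bbox) > tol)) {
      stop("instance ", i, " bbox is not tight: stored ",
           paste(round(inst$bbox, 2), collapse = ","), " vs mask ",
           paste(bb, collapse = ","))
    }
    if (!is.na(inst$area) && abs(sum(mask) - inst$area) > max(tol, 0.02 * inst$area)) {
      stop("instance ", i, " area mismatch")
    }
  }
  invisible(TRUE)
}

# rasterized masks for all instances of a record
scene_masks <- function(record) {
  lapply(record$instances, function(inst) {
    polygons_to_mask(inst$polygons, record$height, record$width)
  })
}
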