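test_that("load_coco groups annotations by image and preserves polygons", {
  dir <- withr::local_tempdir()
  path <- make_coco_fixture(dir)
  recs <- load_coco(path)
  expect_length(recs, 2)
  expect_equal(vapply(recs, function(r) length(r$instances), numeric(1)),
               c(2, 1))
  # verbatim polygon preservation
  expect_equal(recs[[1]]$instances[[1]]$polygons[[1]][, "x"],
               c(4, 12.5, 12.5, 4))
  expect_equal(recs[[1]]$instances[[1]]$polygons[[1]][, "y"],
               c(4, 4, 10.25, 10.25))
})

test_that("load_coco reports malformed or inconsistent files", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.json")
  jsonlite::write_json(list(images = list(), annotations = list()), bad,
                       auto_unbox = TRUE)
  expect_error(load_coco(bad), "categories")
  orphan <- file.path(dir, "orphan.json")
  jsonlite::write_json(list(
    images = list(list(id = 1, width = 8, height = 8, file_name = "x.png")),
    annotations = list(list(id = 1, image_id = 99, category_id = 1,
                            segmentation = list(c(1, 1, 4, 1, 4, 4)),
                            bbox = c(1, 1, 3, 3), area = 9, iscrowd = 0)),
    categories = list(list(id = 1, name = "sheep"))), orphan,
    auto_unbox = TRUE)
  expect_error(load_coco(orphan), "unknown image_id")
})

test_that("empty annotation lists give records with no instances", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "empty.json")
  jsonlite::write_json(list(
    images = list(list(id = 5, width = 16, height = 16, file_name = "a.png")),
    annotations = list(),
    categories = list(list(id = 1, name = "sheep"))), p, auto_unbox = TRUE)
  recs <- load_coco(p)
  expect_length(recs, 1)
  expect_length(recs[[1]]$instances, 0)
})

test_that("write/load round-trip is lossless on ids, boxes and polygons", {
  dir <- withr::local_tempdir()
  path <- make_coco_fixture(dir)
  recs <- load_coco(path)
  path2 <- file.path(dir, "rt.json")
  write_coco(recs, path2)
  recs2 <- load_coco(path2)
  for (i in seq_along(recs)) {
    expect_identical(recs2[[i]]$image_id, recs[[i]]$image_id)
    for (j in seq_along(recs[[i]]$instances)) {
      expect_equal(recs2[[i]]$instances[[j]]$bbox, recs[[i]]$instances[[j]]$bbox)
      expect_equal(unname(recs2[[i]]$instances[[j]]$polygons[[1]]),
                   unname(recs[[i]]$instances[[j]]$polygons[[1]]))
    }
  }
  # serialization is deterministic: writing the reloaded records again
  # reproduces the file byte for byte
  path3 <- file.path(dir, "rt2.json")
  write_coco(recs2, path3)
  expect_identical(readBin(path2, "raw", file.size(path2)),
                   readBin(path3, "raw", file.size(path3)))
})

test_that("write_coco numbers annotations from 1 and rejects duplicate ids", {
  dir <- withr::local_tempdir()
  r <- new_scene_record(1, 16, 16, NULL, list(
    new_instance(1, list(cbind(x = c(2, 9, 9, 2), y = c(2, 2, 9, 9))),
                 c(2, 2, 7, 7), 49)))
  p <- file.path(dir, "one.json")
  write_coco(list(r), p)
  doc <- jsonlite::fromJSON(p, simplifyVector = FALSE)
  expect_length(doc$annotations, 1)
  expect_equal(doc$annotations[[1]]$id, 1)
  p2 <- file.path(dir, "dup.json")
  expect_error(write_coco(list(r, r), p2), "duplicate")
  # empty record list still writes a parseable file
  p3 <- file.path(dir, "none.json")
  write_coco(list(), p3)
  expect_silent(jsonlite::fromJSON(p3, simplifyVector = FALSE))
})

test_that("uncompressed RLE segmentations decode to equivalent polygons", {
  # a 2x2 block at rows 2:3, cols 2:3 of a 4x4 canvas, column-major runs
  counts <- c(5, 2, 2, 2, 5)
  mask <- flockseg:::rle_to_mask(counts, c(4, 4))
  expect_equal(sum(mask), 4)
  dir <- withr::local_tempdir()
  p <- file.path(dir, "rle.json")
  jsonlite::write_json(list(
    images = list(list(id = 1, width = 4, height = 4, file_name = "a.png")),
    annotations = list(list(id = 1, image_id = 1, category_id = 1,
                            segmentation = list(counts = counts, size = c(4, 4)),
                            bbox = c(1, 1, 2, 2), area = 4, iscrowd = 0)),
    categories = list(list(id = 1, name = "sheep"))), p, auto_unbox = TRUE)
  recs <- load_coco(p)
  m2 <- polygons_to_mask(recs[[1]]$instances[[1]]$polygons, 4, 4)
  expect_identical(unname(m2), unname(mask))
})

test_that("split sizes follow nearest-integer rounding with train remainder", {
  sp <- split_dataset(seq_len(1396), c(6, 2, 2), seed = 1)
  expect_equal(lengths(sp), c(train = 838, val = 279, test = 279))
  sp10 <- split_dataset(seq_len(10), c(6, 2, 2), seed = 3)
  expect_equal(lengths(sp10), c(train = 6, val = 2, test = 2))
})

test_that("split is a partition with seed-independent sizes", {
  for (seed in 0:99) {
    sp <- split_dataset(seq_len(7), c(6, 2, 2), seed = seed)
    all_ids <- c(sp$train, sp$val, sp$test)
    expect_equal(sort(all_ids), 1:7)
    expect_equal(lengths(sp), c(train = 5, val = 1, test = 1))
  }
  # same seed, same split
  expect_identical(split_dataset(1:50, seed = 12), split_dataset(1:50, seed = 12))
  expect_error(split_dataset(1:2), "at least 3")
  expect_error(split_dataset(1:5, c(1, 0, 1)), "positive")
})

test_that("rasterization matches the point-in-polygon oracle everywhere", {
  sq <- cbind(x = c(1, 5, 5, 1), y = c(1, 1, 5, 5))
  m <- polygons_to_mask(sq, 8, 8)
  expect_identical(unname(m), unname(oracle_rasterize(sq, 8, 8)))
  expect_equal(sum(m), 16)
  set.seed(20)
  for (i in 1:50) {
    nv <- sample(3:9, 1)
    poly <- cbind(x = runif(nv, 0, 16), y = runif(nv, 0, 16))
    m <- polygons_to_mask(poly, 16, 16)
    expect_identical(unname(m), unname(oracle_rasterize(poly, 16, 16)),
                     label = paste("random polygon", i))
  }
})

test_that("degenerate and disjoint polygons rasterize as expected", {
  degen <- cbind(x = c(3, 3, 3), y = c(1, 5, 9))
  expect_equal(sum(polygons_to_mask(degen, 12, 12)), 0)
  two <- list(cbind(x = c(1, 4, 4, 1), y = c(1, 1, 4, 4)),
              cbind(x = c(6, 10, 10, 6), y = c(6, 6, 10, 10)))
  m <- polygons_to_mask(two, 12, 12)
  expect_equal(sum(m),
               sum(polygons_to_mask(two[[1]], 12, 12)) +
                 sum(polygons_to_mask(two[[2]], 12, 12)))
  expect_warning(polygons_to_mask(cbind(x = c(-3, 5, 5), y = c(1, 1, 5)), 8, 8),
                 "clamp")
})

test_that("mask_to_bbox is the coordinate-range box and flags empty masks", {
  m <- matrix(FALSE, 8, 10)
  m[4, 6] <- TRUE
  expect_equal(mask_to_bbox(m), c(x = 5, y = 3, w = 1, h = 1))
  full <- matrix(TRUE, 6, 9)
  expect_equal(mask_to_bbox(full), c(x = 0, y = 0, w = 9, h = 6))
  set.seed(4)
  for (i in 1:20) {
    rm <- random_mask(9, 11, 0.2)
    if (!any(rm)) next
    idx <- which(rm, arr.ind = TRUE)
    expect_equal(unname(mask_to_bbox(rm)),
                 c(min(idx[, 2]) - 1, min(idx[, 1]) - 1,
                   diff(range(idx[, 2])) + 1, diff(range(idx[, 1])) + 1))
  }
  expect_error(mask_to_bbox(matrix(FALSE, 4, 4)),
               class = "flockseg_empty_mask")
})

test_that("mask -> polygon -> mask round-trip is exact, holes included", {
  # ring with a hole
  ring <- matrix(FALSE, 12, 12)
  ring[3:9, 3:9] <- TRUE
  ring[5:7, 5:7] <- FALSE
  polys <- mask_to_polygons(ring)
  expect_length(polys, 1)
  expect_identical(unname(polygons_to_mask(polys, 12, 12)), unname(ring))
  set.seed(77)
  for (i in 1:40) {
    m <- random_mask(16, 16, runif(1, 0.2, 0.7))
    polys <- mask_to_polygons(m)
    back <- if (length(polys)) polygons_to_mask(polys, 16, 16) else
      matrix(FALSE, 16, 16)
    expect_identical(unname(back), unname(m), label = paste("mask", i))
  }
})
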