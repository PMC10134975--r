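# Quick-look rendering of scenes and predictions with base graphics.

#' Plot a scene with its annotations
#'
#' Renders the image (if present) and overlays each instance's polygon
#' outline and bounding box.
#'
#' @param x a scene record.
#' @param show_boxes draw bounding boxes.
#' @param ... ignored.
#' @return invisibly, `x`.
#' @export
plot.flockseg_scene <- function(x, show_boxes = TRUE, ...) {
  graphics::plot(NA, xlim = c(0, x$width), ylim = c(x$height, 0),
                 asp = 1, xlab = "", ylab = "", axes = FALSE,
                 main = sprintf("scene %d (%d instances)", x$image_id,
                                length(x$instances)))
  if (!is.null(x$image)) {
    graphics::rasterImage(grDevices::as.raster(pmin(pmax(x$image / 255, 0), 1)),
                          0, x$height, x$width, 0, interpolate = FALSE)
  }
  cols <- grDevices::hcl.colors(max(3, length(x$instances)), "Dark 3")
  for (i in seq_along(x$instances)) {
    inst <- x$instances[[i]]
    for (p in inst$polygons) {
      graphics::polygon(p[, 1], p[, 2], border = cols[i], lwd = 2)
    }
    if (show_boxes) {
      b <- inst$bbox
      graphics::rect(b[1], b[2], b[1] + b[3], b[2] + b[4], border = cols[i],
                     lty = 2)
    }
  }
  invisible(x)
}
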