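# Gaussian location heatmaps: the supervision signal for the translation
# support networks. Each box contributes an anisotropic Gaussian bump peaking
# at 1 at the box centre with sigma proportional to the box side lengths;
# bumps are combined by elementwise maximum so values stay in [0, 1], the
# target range of a binary cross-entropy loss.

#' Convert bounding boxes to a Gaussian heatmap
#'
#' For a box with centre `(cx, cy)` and sides `(w, h)`, the bump is
#' `exp(-((u-cx)^2 / (2*sx^2) + (v-cy)^2 / (2*sy^2)))` with
#' `sx = sigma_factor * w`, `sy = sigma_factor * h`. The grid is the
#' elementwise maximum over boxes; an empty box list gives all zeros.
#' Pixel `(row r, col c)` samples the continuous point `(u, v) = (c-1, r-1)`,
#' so an integer-centre box peaks at exactly 1 on its centre pixel.
#'
#' @param boxes list of [bbox()].
#' @param height,width grid size in pixels.
#' @param sigma_factor sigma as a fraction of the box side; the default 1/6
#'   puts +/- 3 sigma at the box edges.
#' @return A `height x width` matrix in `[0, 1]` of class `heatmap_grid`.
#' @export
boxes_to_heatmap <- function(boxes, height, width, sigma_factor = 1 / 6) {
  if (sigma_factor <= 0) stopf("sigma_factor must be > 0")
  grid <- matrix(0, height, width)
  u <- seq_len(width) - 1
  v <- seq_len(height) - 1
  for (b in boxes) {
    stopifnot(inherits(b, "bbox"))
    if (bbox_area(b) <= 0) stopf("zero-area box")
    ctr <- bbox_center(b)
    sx <- sigma_factor * bbox_width(b)
    sy <- sigma_factor * bbox_height(b)
    gu <- exp(-(u - ctr[1])^2 / (2 * sx^2))
    gv <- exp(-(v - ctr[2])^2 / (2 * sy^2))
    bump <- outer(gv, gu)
    grid <- pmax(grid, bump)
  }
  class(grid) <- c("heatmap_grid", class(grid))
  grid
}

#' Heatmaps for a whole annotation set
#'
#' @param annotations named list of [scene_annotation()].
#' @param sigma_factor see [boxes_to_heatmap()].
#' @return Named list of heatmaps keyed by image id.
#' @export
dataset_heatmaps <- function(annotations, sigma_factor = 1 / 6) {
  out <- lapply(annotations, function(ann) {
    stopifnot(inherits(ann, "scene_annotation"))
    if (is.null(ann$height) || is.null(ann$width))
      stopf("annotation '%s' lacks image dimensions", ann$image_id)
    boxes_to_heatmap(ann$boxes, ann$height, ann$width, sigma_factor)
  })
  names(out) <- vapply(annotations, `[[`, character(1), "image_id")
  out
}

#' Persist a heatmap as an 8-bit grayscale PNG
#'
#' Values are stored as `round(255 * g)`; [read_heatmap_png()] inverts the
#' quantisation (exact to 1/510).
#'
#' @param grid heatmap matrix in `[0, 1]`.
#' @param path output PNG path.
#' @export
write_heatmap_png <- function(grid, path) {
  png::writePNG(round(255 * grid) / 255, path)
  invisible(path)
}

#' @rdname write_heatmap_png
#' @return `read_heatmap_png` returns the heatmap matrix.
#' @export
read_heatmap_png <- function(path) {
  g <- png::readPNG(path)
  if (length(dim(g)) == 3L) g <- g[, , 1]
  class(g) <- c("heatmap_grid", class(g))
  g
}
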