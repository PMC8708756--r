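# Assembly of the experiment datasets: R (real), S (synthetic), C (plain
# translator), H (heatmap-supported translator), K (k-cluster translated,
# k outputs per input) and their unions with R, with consistent resizing of
# images, boxes and regenerated heatmaps.

#' Dataset bundle
#'
#' The unit moved between pipeline stages: images, annotations, optional
#' heatmaps, and a provenance record per image (origin id + transform chain).
#'
#' @param name dataset label (e.g. `"S"`, `"H"`, `"K+R"`).
#' @param images named list of `[0, 1]` arrays, or `NULL` for geometry-only
#'   bundles.
#' @param annotations named list of [scene_annotation()]; must cover every
#'   image.
#' @param heatmaps optional named list of heatmap matrices.
#' @param provenance named list of `list(origin =, chain =)`; defaults to
#'   identity provenance.
#' @return An object of class `dataset_bundle`.
#' @export
dataset_bundle <- function(name, images = NULL, annotations = list(),
                           heatmaps = NULL, provenance = NULL) {
  ids <- names(annotations)
  if (!is.null(images)) {
    if (!setequal(names(images), ids))
      stopf("every image needs an annotation record and vice versa")
    images <- images[ids]
  }
  if (is.null(provenance))
    provenance <- stats::setNames(
      lapply(ids, function(i) list(origin = i, chain = "source")), ids)
  if (!all(ids %in% names(provenance)))
    stopf("provenance must cover every image")
  if (!is.null(heatmaps)) heatmaps <- heatmaps[ids]
  structure(list(name = name, images = images, annotations = annotations,
                 heatmaps = heatmaps, provenance = provenance[ids]),
            class = "dataset_bundle")
}

#' @export
print.dataset_bundle <- function(x, ...) {
  n_box <- sum(vapply(x$annotations, function(a) length(a$boxes), numeric(1)))
  cat(sprintf("dataset_bundle '%s': %d images, %d boxes%s\n", x$name,
              length(x$annotations), n_box,
              if (is.null(x$images)) " (geometry only)" else ""))
  invisible(x)
}

dataset_ids <- function(bundle) names(bundle$annotations)

dataset_size <- function(bundle) length(bundle$annotations)

subset_bundle <- function(bundle, ids, name = bundle$name) {
  dataset_bundle(name,
                 images = if (is.null(bundle$images)) NULL else bundle$images[ids],
                 annotations = bundle$annotations[ids],
                 heatmaps = if (is.null(bundle$heatmaps)) NULL else bundle$heatmaps[ids],
                 provenance = bundle$provenance[ids])
}

#' Resize one image and its annotation
#'
#' Bilinear image resize; boxes are scaled by the per-axis factors. Heatmaps
#' are *regenerated* from the scaled boxes rather than interpolated, so peak
#' values stay exactly 1.
#'
#' @param image `[0, 1]` array or `NULL`.
#' @param annotation a [scene_annotation()].
#' @param target_size `(width, height)` in pixels, or one scalar for square.
#' @param sigma_factor passed to [boxes_to_heatmap()] when regenerating.
#' @param heatmap logical: regenerate the heatmap too?
#' @return List with `image`, `annotation` and (optionally) `heatmap`.
#' @export
resize_sample <- function(image, annotation, target_size,
                          sigma_factor = 1 / 6, heatmap = FALSE) {
  if (length(target_size) == 1L) target_size <- c(target_size, target_size)
  tw <- as.integer(target_size[1])
  th <- as.integer(target_size[2])
  if (tw <= 0 || th <= 0) stopf("target_size must be positive")
  ow <- annotation$width
  oh <- annotation$height
  if (ow <= 0 || oh <= 0) stopf("annotation has degenerate dimensions")
  fx <- tw / ow
  fy <- th / oh
  boxes <- lapply(annotation$boxes, function(b)
    bbox(b[["x_min"]] * fx, b[["y_min"]] * fy,
         b[["x_max"]] * fx, b[["y_max"]] * fy))
  ann <- scene_annotation(annotation$image_id, tw, th, boxes)
  out_img <- NULL
  if (!is.null(image)) {
    if (oh == th && ow == tw) {
      out_img <- image
    } else {
      out_img <- array(0, c(th, tw, 3))
      for (c3 in 1:3)
        out_img[, , c3] <- as.matrix(
          EBImage::resize(EBImage::Image(image[, , c3]), w = th, h = tw))
      out_img <- clamp(out_img, 0, 1)
    }
  }
  out <- list(image = out_img, annotation = ann)
  if (heatmap) out$heatmap <- boxes_to_heatmap(ann$boxes, th, tw, sigma_factor)
  out
}

#' Resize a whole bundle
#'
#' @param bundle a [dataset_bundle()].
#' @param target_size pixels (scalar or `(w, h)`); the published pipeline
#'   resizes everything to 400.
#' @param sigma_factor heatmap regeneration sigma.
#' @return The resized bundle (heatmaps regenerated when present before).
#' @export
resize_bundle <- function(bundle, target_size, sigma_factor = 1 / 6) {
  want_hm <- !is.null(bundle$heatmaps)
  images <- list()
  anns <- list()
  hms <- if (want_hm) list() else NULL
  for (id in dataset_ids(bundle)) {
    r <- resize_sample(bundle$images[[id]], bundle$annotations[[id]],
                       target_size, sigma_factor, heatmap = want_hm)
    if (!is.null(r$image)) images[[id]] <- r$image
    anns[[id]] <- r$annotation
    if (want_hm) hms[[id]] <- r$heatmap
  }
  prov <- lapply(bundle$provenance, function(p) {
    p$chain <- paste(p$chain, sprintf("resize_%s", paste(target_size, collapse = "x")),
                     sep = "|")
    p
  })
  dataset_bundle(bundle$name, images = if (length(images)) images else NULL,
                 annotations = anns, heatmaps = hms, provenance = prov)
}

#' Build a translated dataset (C or H)
#'
#' Translates every synthetic image to the target style with a trained model
#' set; annotations are copied verbatim from the source (translation
#' preserves geometry by construction and translated outputs are never
#' re-annotated).
#'
#' @param name `"C"` (requires a model trained with `lambda_heatmap = 0`) or
#'   `"H"` (requires a heatmap-supported model).
#' @param s the synthetic [dataset_bundle()].
#' @param models a trained `model_set`.
#' @param checkpoint_id label recorded in provenance.
#' @return A bundle of the same size with translated images.
#' @export
build_translated <- function(name = c("H", "C"), s, models,
                             checkpoint_id = "checkpoint") {
  name <- match.arg(name)
  lh <- models$config$lambda_heatmap
  if (name == "C" && lh != 0)
    stopf("dataset C requires a plain model (lambda_heatmap = 0), got %g", lh)
  if (name == "H" && lh == 0)
    stopf("dataset H requires a heatmap-supported model (lambda_heatmap > 0)")
  if (is.null(s$images)) stopf("source bundle has no images")
  imgs <- translate_images(models, s$images, "s2r")
  prov <- lapply(dataset_ids(s), function(id) {
    p <- s$provenance[[id]]
    p$chain <- paste(p$chain, sprintf("translate_s2r[%s]", checkpoint_id),
                     sep = "|")
    p
  })
  names(prov) <- dataset_ids(s)
  dataset_bundle(name, images = imgs, annotations = s$annotations,
                 heatmaps = s$heatmaps, provenance = prov)
}

#' Build the clustered-translation dataset K
#'
#' Translates every synthetic image once per cluster model, multiplying the
#' dataset size by `k` (with the published k = 4, quadrupling it). Image ids
#' gain a `_c<j>` suffix; every source annotation is duplicated per cluster.
#'
#' @param s the synthetic [dataset_bundle()].
#' @param cluster_models list of `k` trained `model_set`s, one per
#'   appearance cluster.
#' @return A bundle with `k * |S|` images.
#' @export
build_K <- function(s, cluster_models) {
  k <- length(cluster_models)
  if (k < 1L) stopf("need at least one cluster model")
  parts <- lapply(seq_len(k), function(j) {
    h <- build_translated("H", s, cluster_models[[j]],
                          checkpoint_id = sprintf("cluster%d", j - 1L))
    rename_bundle_ids(h, function(id) sprintf("%s_c%d", id, j - 1L))
  })
  out <- Reduce(function(a, b) combine_bundles(a, b, name = "K"), parts)
  out$name <- "K"
  out
}

rename_bundle_ids <- function(bundle, f) {
  ids <- dataset_ids(bundle)
  new_ids <- vapply(ids, f, character(1))
  anns <- bundle$annotations
  names(anns) <- new_ids
  for (i in seq_along(anns)) anns[[i]]$image_id <- new_ids[[i]]
  imgs <- bundle$images
  if (!is.null(imgs)) names(imgs) <- new_ids
  hms <- bundle$heatmaps
  if (!is.null(hms)) names(hms) <- new_ids
  prov <- bundle$provenance
  names(prov) <- new_ids
  dataset_bundle(bundle$name, imgs, anns, hms, prov)
}

#' Combine two bundles
#'
#' Sizes add; annotations are preserved; id collisions on the second bundle
#' get a disambiguating suffix.
#'
#' @param a,b [dataset_bundle()]s.
#' @param name label of the union (default `"a+b"`).
#' @return The combined bundle.
#' @export
combine_bundles <- function(a, b, name = paste(a$name, b$name, sep = "+")) {
  clash <- intersect(dataset_ids(a), dataset_ids(b))
  if (length(clash))
    b <- rename_bundle_ids(b, function(id)
      if (id %in% clash) paste0(id, "_b") else id)
  has_img <- !is.null(a$images) && !is.null(b$images)
  has_hm <- !is.null(a$heatmaps) && !is.null(b$heatmaps)
  dataset_bundle(
    name,
    images = if (has_img) c(a$images, b$images) else NULL,
    annotations = c(a$annotations, b$annotations),
    heatmaps = if (has_hm) c(a$heatmaps, b$heatmaps) else NULL,
    provenance = c(a$provenance, b$provenance))
}

#' Serialise / load a bundle (images dir + annotations CSV + manifest)
#'
#' Images are written as PNG, annotations as internal-dialect CSV, heatmaps
#' as grayscale PNG, and the manifest (name + provenance) as JSON. The
#' round trip is lossless up to 8-bit image quantisation; annotations are
#' exact.
#'
#' @param bundle a [dataset_bundle()].
#' @param dir output directory.
#' @export
save_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(bundle$images)) {
    img_dir <- file.path(dir, "images")
    dir.create(img_dir, showWarnings = FALSE)
    for (id in names(bundle$images))
      png::writePNG(bundle$images[[id]], file.path(img_dir, paste0(id, ".png")))
  }
  if (!is.null(bundle$heatmaps)) {
    hm_dir <- file.path(dir, "heatmaps")
    dir.create(hm_dir, showWarnings = FALSE)
    for (id in names(bundle$heatmaps))
      write_heatmap_png(bundle$heatmaps[[id]],
                        file.path(hm_dir, paste0(id, ".png")))
  }
  write_annotations_csv(bundle$annotations, file.path(dir, "annotations.csv"))
  # keep zero-box images recoverable: record all ids and dims in the manifest
  dims <- lapply(bundle$annotations, function(a)
    list(width = a$width, height = a$height))
  jsonlite::write_json(
    list(name = bundle$name, ids = dataset_ids(bundle), dims = dims,
         provenance = bundle$provenance),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}

#' @rdname save_bundle
#' @return `load_bundle` returns the reconstructed bundle.
#' @export
load_bundle <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = FALSE)
  anns <- read_annotations_csv(file.path(dir, "annotations.csv"))
  ids <- vapply(man$ids, identity, character(1))
  for (id in ids) {
    if (is.null(anns[[id]]))
      anns[[id]] <- scene_annotation(id, man$dims[[id]]$width,
                                     man$dims[[id]]$height, list())
  }
  anns <- anns[ids]
  img_dir <- file.path(dir, "images")
  images <- NULL
  if (dir.exists(img_dir)) {
    images <- lapply(ids, function(id)
      png::readPNG(file.path(img_dir, paste0(id, ".png"))))
    names(images) <- ids
  }
  hm_dir <- file.path(dir, "heatmaps")
  heatmaps <- NULL
  if (dir.exists(hm_dir)) {
    heatmaps <- lapply(ids, function(id)
      read_heatmap_png(file.path(hm_dir, paste0(id, ".png"))))
    names(heatmaps) <- ids
  }
  prov <- lapply(man$provenance, function(p)
    list(origin = p$origin, chain = p$chain))
  names(prov) <- names(man$provenance)
  dataset_bundle(man$name, images, anns, heatmaps, prov)
}
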