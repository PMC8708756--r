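# Procedural wheat-field scene generation: plant placement, wind sampling,
# stem growth and head attachment, plus derivation of per-image annotations.

#' Scene specification
#'
#' @param seed integer root seed; scene `i` of a dataset is generated from
#'   child seed `seed + i` so every scene is independently reproducible.
#' @param n_plants fixed plant count, or `NULL` to sample uniformly from
#'   `plant_range`.
#' @param plant_range inclusive `(min, max)` plant-count range; the default
#'   `(30, 60)` reproduces field-scale head density.
#' @param field_extent `(x, y)` extent of the plot in world units, centred on
#'   the origin.
#' @param wind a [wind_state()], or `"sample"` to draw speed ~ U(0, 1) and
#'   direction ~ U(0, 2*pi) per scene.
#' @param background_density scalar in `[0, 1]` controlling how much ground
#'   foliage the renderer adds.
#' @param lsys the stem grammar, an [lsystem_spec()].
#' @param head_length,head_radius head ellipsoid dimensions (world units).
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(seed = 1L, n_plants = NULL, plant_range = c(30L, 60L),
                       field_extent = c(1.6, 1.6), wind = "sample",
                       background_density = 0.5,
                       lsys = lsystem_spec(),
                       head_length = 0.14, head_radius = 0.04) {
  if (plant_range[1] > plant_range[2]) stopf("plant_range min must be <= max")
  if (!is.null(n_plants) &&
      (n_plants < plant_range[1] || n_plants > plant_range[2]))
    stopf("n_plants must lie within plant_range")
  if (any(field_extent <= 0)) stopf("field_extent must be positive")
  if (background_density < 0 || background_density > 1)
    stopf("background_density must be in [0, 1]")
  structure(
    list(seed = as.integer(seed), n_plants = n_plants,
         plant_range = as.integer(plant_range),
         field_extent = as.numeric(field_extent), wind = wind,
         background_density = background_density, lsys = lsys,
         head_length = head_length, head_radius = head_radius),
    class = "scene_spec")
}

#' Generate one wheat scene
#'
#' Draws the wind state and plant count, places plants uniformly over the
#' field, grows each stem by L-system expansion with its wind bend schedule,
#' and attaches a head ellipsoid at each stem tip continuing the stem
#' direction. The per-bend-symbol angle of the grammar is scaled by the wind
#' speed, so in still air every stem is exactly vertical. Deterministic in
#' `spec$seed`: the same spec yields a bitwise-identical scene.
#'
#' @param spec a [scene_spec()].
#' @return An object of class `wheat_scene`: lists `stems` and `heads`, the
#'   realised `wind`, plant `bases`, and the generating `spec`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    wind <- spec$wind
    if (identical(wind, "sample"))
      wind <- wind_state(stats::runif(1), stats::runif(1, 0, 2 * pi))
    n <- spec$n_plants %||%
      sample(seq(spec$plant_range[1], spec$plant_range[2]), 1L)
    ex <- spec$field_extent
    bases <- cbind(stats::runif(n, -ex[1] / 2, ex[1] / 2),
                   stats::runif(n, -ex[2] / 2, ex[2] / 2), 0)
    symbols <- expand_lsystem(spec$lsys)
    stems <- vector("list", n)
    heads <- vector("list", n)
    for (i in seq_len(n)) {
      bends <- wind_modulate(spec$lsys, wind)
      stem <- interpret_stem(symbols, bends, bases[i, ], spec$lsys,
                             bend_scale = wind$speed)
      # mild per-plant size variation
      len <- spec$head_length * stats::runif(1, 0.85, 1.15)
      rad <- spec$head_radius * stats::runif(1, 0.85, 1.15)
      stems[[i]] <- stem
      heads[[i]] <- head_geometry(stem$head_anchor, stem$head_axis, len, rad)
    }
    structure(list(stems = stems, heads = heads, wind = wind, bases = bases,
                   spec = spec),
              class = "wheat_scene")
  })
}

#' Per-image annotation record
#'
#' @param image_id image identifier string.
#' @param width,height image dimensions in pixels.
#' @param boxes list of [bbox()] objects, each valid against the dimensions.
#' @return An object of class `scene_annotation`.
#' @export
scene_annotation <- function(image_id, width, height, boxes = list()) {
  for (b in boxes) {
    stopifnot(inherits(b, "bbox"))
    if (b[["x_min"]] < 0 || b[["x_max"]] > width ||
        b[["y_min"]] < 0 || b[["y_max"]] > height)
      stopf("box outside image bounds for '%s'", image_id)
  }
  structure(list(image_id = image_id, width = as.integer(width),
                 height = as.integer(height), boxes = boxes),
            class = "scene_annotation")
}

#' Derive the bounding-box annotation of a scene
#'
#' Projects every head through the camera and keeps the boxes passing the
#' visibility rule of [compute_bbox()].
#'
#' @param scene a [wheat_scene()].
#' @param cam a [camera_model()].
#' @param image_id identifier for the annotation record.
#' @param ... passed to [compute_bbox()] (e.g. `id_buffer`).
#' @return A [scene_annotation()]. The indices of the kept heads are attached
#'   as attribute `head_ids`.
#' @export
annotate_scene <- function(scene, cam, image_id = "scene", ...) {
  stopifnot(inherits(scene, "wheat_scene"))
  boxes <- list()
  ids <- integer(0)
  for (i in seq_along(scene$heads)) {
    b <- compute_bbox(cam, scene$heads[[i]], head_id = i, ...)
    if (!is.null(b)) {
      boxes[[length(boxes) + 1L]] <- b
      ids <- c(ids, i)
    }
  }
  ann <- scene_annotation(image_id, cam$width, cam$height, boxes)
  attr(ann, "head_ids") <- ids
  ann
}

#' Generate a synthetic annotated dataset
#'
#' Runs scene generation, (optionally) rendering, and annotation for
#' `n_images` scenes under child seeds `seed + 1 .. seed + n_images`.
#'
#' @param n_images number of scenes.
#' @param seed root seed.
#' @param cam camera; default [overhead_camera()] at the requested size.
#' @param width,height image size in pixels when `cam` is not given.
#' @param render if `FALSE`, only geometry and annotations are produced
#'   (images are `NULL`) — used for dataset-scale annotation counts.
#' @param style render style, see [render_style()].
#' @param spec base [scene_spec()]; its seed is overridden per scene.
#' @return A `dataset_bundle` (see [dataset_bundle()]) with images (unless
#'   `render = FALSE`), annotations and provenance.
#' @export
generate_dataset <- function(n_images, seed = 1L, cam = NULL,
                             width = 400L, height = 400L, render = TRUE,
                             style = render_style(), spec = scene_spec()) {
  cam <- cam %||% overhead_camera(width = width, height = height)
  images <- list()
  annotations <- list()
  provenance <- list()
  for (i in seq_len(n_images)) {
    sp <- spec
    sp$seed <- as.integer(seed + i)
    scene <- generate_scene(sp)
    id <- sprintf("synth_%05d", i)
    if (render) {
      r <- render_scene(scene, cam, style = style, seed = sp$seed)
      ann <- annotate_scene(scene, cam, image_id = id,
                            id_buffer = r$id_buffer)
      images[[id]] <- r$image
    } else {
      ann <- annotate_scene(scene, cam, image_id = id)
    }
    annotations[[id]] <- ann
    provenance[[id]] <- list(origin = id, chain = "scene_synthesis")
  }
  dataset_bundle(name = "S", images = if (render) images else NULL,
                 annotations = annotations, provenance = provenance)
}
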