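# Programmatic fixtures: everything the tests and smoke runs need is built
# in code at run time, no stored data.

#' Two-style translation fixture
#'
#' Renders the same kind of small scenes in the two render styles to emulate
#' a two-domain setting (source = `"synthetic"` palette, target = `"field"`
#' palette) with heatmap labels on both sides. Scenes are small (few plants)
#' so head structure is resolvable at tiny image sizes.
#'
#' @param n_per_domain images per domain.
#' @param size square image size in pixels.
#' @param seed root seed; the two domains draw disjoint scene seeds.
#' @param n_plants plants per fixture scene.
#' @return List with `source` and `target`, each
#'   `list(images =, heatmaps =, annotations =)`.
#' @export
make_two_style_fixture <- function(n_per_domain = 32L, size = 64L, seed = 1L,
                                   n_plants = 6L) {
  cam <- overhead_camera(altitude = 3, focal_px = size * 1.25,
                         width = size, height = size)
  build_domain <- function(style, seed0, tag) {
    images <- list()
    hms <- list()
    anns <- list()
    for (i in seq_len(n_per_domain)) {
      sp <- scene_spec(seed = seed0 + i, n_plants = n_plants,
                       plant_range = c(n_plants, n_plants),
                       field_extent = c(1.6, 1.6),
                       background_density = 0.3,
                       head_length = 0.22, head_radius = 0.07)
      scene <- generate_scene(sp)
      r <- render_scene(scene, cam, style = style)
      id <- sprintf("%s_%03d", tag, i)
      ann <- annotate_scene(scene, cam, image_id = id)
      images[[id]] <- r$image
      hms[[id]] <- boxes_to_heatmap(ann$boxes, size, size)
      anns[[id]] <- ann
    }
    list(images = images, heatmaps = hms, annotations = anns)
  }
  list(source = build_domain(render_style("synthetic"), seed * 10000L, "src"),
       target = build_domain(render_style("field"), seed * 10000L + 5000L,
                             "tgt"))
}

#' Isotropic Gaussian blob features
#'
#' Classic separable-cluster fixture for K-means recovery tests: `k` blobs
#' with centres at mutual distance >= `spacing` and isotropic spread
#' `sigma`.
#'
#' @param k number of blobs.
#' @param n_per_blob points per blob.
#' @param dim feature dimensionality.
#' @param sigma within-blob standard deviation.
#' @param spacing distance between consecutive blob centres.
#' @param seed RNG seed.
#' @return List: `features` (matrix with rownames), `labels` (0-based true
#'   blob index).
#' @export
make_blob_features <- function(k = 4L, n_per_blob = 50L, dim = 8L,
                               sigma = 0.1, spacing = 10, seed = 1L) {
  with_seed(seed, {
    centres <- matrix(0, k, dim)
    for (j in seq_len(k)) centres[j, ] <- stats::rnorm(dim)
    # place centres on distinct radii so all pairs are >= spacing apart
    centres <- centres / sqrt(rowSums(centres^2)) * (spacing * seq_len(k))
    x <- do.call(rbind, lapply(seq_len(k), function(j) {
      matrix(stats::rnorm(n_per_blob * dim, sd = sigma), n_per_blob, dim) +
        matrix(centres[j, ], n_per_blob, dim, byrow = TRUE)
    }))
    rownames(x) <- sprintf("pt_%04d", seq_len(nrow(x)))
    list(features = x, labels = rep(seq_len(k) - 1L, each = n_per_blob),
         centres = centres)
  })
}
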