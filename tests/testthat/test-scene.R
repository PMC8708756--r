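test_that("pinhole projection matches closed forms", {
  cam <- camera_model(c(0, 0, 10), c(0, 0, -1), c(0, 1, 0), focal_px = 400,
                      width = 400, height = 400,
                      principal_point = c(200, 200))
  # optical axis maps to the principal point at any depth
  for (z in c(9, 5, 1)) {
    expect_equal(project_point(cam, c(0, 0, z)), c(200, 200),
                 tolerance = 1e-12)
  }
  # off-axis point: u = u0 + f * x / z
  expect_equal(project_point(cam, c(1, 0, 0)), c(240, 200),
               tolerance = 1e-9)
  # point at the camera centre is degenerate
  expect_identical(project_point(cam, c(0, 0, 10)), "behind")
  expect_identical(project_point(cam, c(0, 0, 11)), "behind")
})

test_that("projection obeys similar-triangles scaling", {
  cam <- overhead_camera(altitude = 10, focal_px = 300, width = 200,
                         height = 200)
  p1 <- project_point(cam, c(0.5, -0.3, 5))  # depth 5
  p2 <- project_point(cam, c(0.5, -0.3, 0))  # depth 10: offsets halve
  off1 <- p1 - cam$principal_point
  off2 <- p2 - cam$principal_point
  expect_equal(off1, 2 * off2, tolerance = 1e-9)
})

test_that("spherical head bbox matches the analytic projection", {
  f <- 400
  z <- 5
  r <- 0.1
  cam <- camera_model(c(0, 0, 0), c(0, 0, 1), c(0, -1, 0), focal_px = f,
                      width = 400, height = 400)
  # sphere: length = 2 * radius, centred on the optical axis at depth z
  head <- head_geometry(anchor = c(0, 0, z - r), axis = c(0, 0, 1),
                        length = 2 * r, radius = r)
  b <- compute_bbox(cam, head, n_samples = 64L)
  half_w <- f * r / z
  ctr <- bbox_center(b)
  # centre within surface-sampling error of the principal point
  expect_lt(max(abs(ctr - cam$principal_point)), 0.5)
  expect_equal(bbox_width(b) / 2, half_w, tolerance = 0.02 * half_w)
  expect_equal(bbox_height(b) / 2, half_w, tolerance = 0.02 * half_w)
})

test_that("bbox visibility rules: behind camera, clipping, bounds", {
  cam <- overhead_camera(altitude = 3, focal_px = 500, width = 400,
                         height = 400)
  behind <- head_geometry(c(0, 0, 5), c(0, 0, 1), 0.2, 0.05)
  expect_null(compute_bbox(cam, behind))

  # head straddling the frame edge: clipped, still in bounds
  # frame half-width in world units at the head's depth is ~0.76
  edge <- head_geometry(c(0.75, 0, 1), c(0, 0, 1), 0.2, 0.08)
  b <- compute_bbox(cam, edge)
  expect_false(is.null(b))
  expect_lte(b[["x_max"]], 400)
  expect_gte(b[["x_min"]], 0)

  # far outside: dropped
  gone <- head_geometry(c(3, 3, 1), c(0, 0, 1), 0.2, 0.05)
  expect_null(compute_bbox(cam, gone))
})

test_that("scene generation is seeded, in range, and wind-consistent", {
  spec <- scene_spec(seed = 21L)
  s1 <- generate_scene(spec)
  s2 <- generate_scene(spec)
  expect_identical(s1, s2)
  expect_gte(length(s1$heads), 30)
  expect_lte(length(s1$heads), 60)

  # zero wind leaves every stem perfectly vertical
  calm <- generate_scene(scene_spec(seed = 3L, wind = wind_state(0, 1)))
  for (st in calm$stems) {
    tip_xy <- st$head_anchor[1:2] - st$polyline[1, 1:2]
    expect_lt(sqrt(sum(tip_xy^2)), 1e-9)
  }
})

test_that("every emitted box is in bounds with positive area", {
  cam <- overhead_camera()
  for (seed in 1:5) {
    ann <- annotate_scene(generate_scene(scene_spec(seed = seed)), cam)
    for (b in ann$boxes) {
      expect_gte(b[["x_min"]], 0)
      expect_gte(b[["y_min"]], 0)
      expect_lte(b[["x_max"]], cam$width)
      expect_lte(b[["y_max"]], cam$height)
      expect_gt(bbox_area(b), 0)
    }
  }
})

test_that("mean plant count matches the discrete-uniform expectation", {
  counts <- vapply(1:400, function(i)
    length(generate_scene(scene_spec(seed = 5000L + i,
                                     field_extent = c(1, 1),
                                     lsys = lsystem_spec(iterations = 0L)))$heads),
    numeric(1))
  expect_gte(min(counts), 30)
  expect_lte(max(counts), 60)
  # mean of U{30..60} is 45; se over 400 draws ~ 0.45
  expect_equal(mean(counts), 45, tolerance = 1 / 45)
})

test_that("rendering is deterministic and head footprints match boxes", {
  cam <- tiny_cam(64L)
  spec <- scene_spec(seed = 9L, n_plants = 3L, plant_range = c(3L, 3L),
                     field_extent = c(1, 1), head_length = 0.25,
                     head_radius = 0.08)
  scene <- generate_scene(spec)
  r1 <- render_scene(scene, cam)
  r2 <- render_scene(scene, cam)
  expect_identical(r1$image, r2$image)
  expect_true(all(r1$image >= 0 & r1$image <= 1))

  ann <- annotate_scene(scene, cam, id_buffer = r1$id_buffer)
  ids <- attr(ann, "head_ids")
  # at least half of each head's rendered pixels fall inside its box
  for (j in seq_along(ids)) {
    px <- which(r1$id_buffer == ids[j], arr.ind = TRUE)
    if (nrow(px) < 4) next
    b <- ann$boxes[[j]]
    inside <- px[, 2] - 0.5 >= b[["x_min"]] & px[, 2] - 0.5 <= b[["x_max"]] &
      px[, 1] - 0.5 >= b[["y_min"]] & px[, 1] - 0.5 <= b[["y_max"]]
    expect_gte(mean(inside), 0.5)
  }

  # an empty scene renders pure background: no id-buffer hits
  empty <- generate_scene(scene_spec(seed = 2L, n_plants = 30L))
  empty$heads <- list()
  empty$stems <- list()
  r0 <- render_scene(empty, cam)
  expect_true(all(r0$id_buffer == 0L))
})

test_that("annotation CSVs round-trip in both dialects", {
  set.seed(4)
  anns <- lapply(1:20, function(i) {
    n_box <- sample(1:5, 1)
    boxes <- lapply(seq_len(n_box), function(j) {
      x0 <- runif(1, 0, 350)
      y0 <- runif(1, 0, 350)
      bbox(x0, y0, x0 + runif(1, 2, 45), y0 + runif(1, 2, 45))
    })
    scene_annotation(sprintf("img_%03d", i), 400L, 400L, boxes)
  })
  names(anns) <- vapply(anns, `[[`, character(1), "image_id")

  for (dialect in c("internal", "gwhc")) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_annotations_csv(anns, path, dialect = dialect)
    back <- read_annotations_csv(path)
    expect_identical(names(back), names(anns))
    for (id in names(anns)) {
      expect_equal(length(back[[id]]$boxes), length(anns[[id]]$boxes))
      for (j in seq_along(anns[[id]]$boxes))
        expect_equal(as.numeric(back[[id]]$boxes[[j]]),
                     as.numeric(anns[[id]]$boxes[[j]]), tolerance = 1e-6)
    }
  }

  # empty annotation set: header-only file, empty round trip
  path <- withr::local_tempfile(fileext = ".csv")
  write_annotations_csv(list(), path)
  expect_length(read_annotations_csv(path), 0)

  # one image with two boxes produces two data rows (internal dialect)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_annotations_csv(anns[1], path2)
  n_lines <- length(readLines(path2))
  expect_equal(n_lines - 1L, length(anns[[1]]$boxes))

  # malformed rows are rejected with a row reference
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("image_id,width,height,x_min,y_min,x_max,y_max",
               "a,400,400,10,10,5,20"), bad)
  expect_error(read_annotations_csv(bad), "row 1")
})
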