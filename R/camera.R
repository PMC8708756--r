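# Pinhole camera model and projection of scene geometry to pixel space.
#
# Camera coordinates follow the usual computer-vision convention: x right,
# y down, z forward; pixels are continuous, 0-based, origin top-left.

#' Pinhole camera model
#'
#' @param position camera centre in world coordinates (length-3).
#' @param forward unit viewing direction (world).
#' @param up unit up direction (world); must be orthogonal to `forward`. The
#'   image y axis points along `-up`.
#' @param focal_px focal length in pixels (> 0).
#' @param principal_point `(u0, v0)` in pixels; defaults to the image centre.
#' @param width,height image dimensions in pixels.
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(position, forward, up, focal_px,
                         width, height,
                         principal_point = c(width / 2, height / 2)) {
  forward <- unit3(as.numeric(forward))
  up <- unit3(as.numeric(up))
  if (abs(sum(forward * up)) > 1e-9)
    stopf("forward and up must be orthogonal")
  if (!is_scalar_num(focal_px) || focal_px <= 0)
    stopf("focal_px must be > 0")
  right <- unit3(pracma_cross(forward, up))
  # rows: camera x (right), y (down = -up), z (forward)
  rot <- rbind(right, -up, forward)
  dimnames(rot) <- NULL
  structure(
    list(position = as.numeric(position), forward = forward, up = up,
         right = right, rot = rot, focal_px = focal_px,
         principal_point = as.numeric(principal_point),
         width = as.integer(width), height = as.integer(height)),
    class = "camera_model")
}

#' Overhead camera looking straight down at the field
#'
#' Convenience constructor matching the top-down acquisition geometry of
#' wheat-head datasets: the camera sits on the +z axis at `altitude` looking
#' along -z, with image y running along world -y.
#'
#' @param altitude camera height above the ground plane (world units).
#' @param focal_px focal length in pixels; the default scales with the image
#'   width so the field of view is the same at every output size.
#' @param width,height image size in pixels.
#' @return A [camera_model()].
#' @export
overhead_camera <- function(altitude = 3, focal_px = 1.25 * width,
                            width = 400, height = 400) {
  camera_model(position = c(0, 0, altitude), forward = c(0, 0, -1),
               up = c(0, 1, 0), focal_px = focal_px,
               width = width, height = height)
}

# world point(s) -> camera frame; p is n x 3, returns n x 3 (x right, y down,
# z forward)
to_camera <- function(cam, p) {
  p <- matrix(p, ncol = 3L)
  sweep(p, 2L, cam$position) %*% t(cam$rot)
}

#' Project a world point through the camera
#'
#' Standard pinhole projection `u = u0 + f*x/z`, `v = v0 + f*y/z` with the
#' point expressed in camera coordinates. Points at or behind the camera
#' plane (`z <= 0`) return the sentinel `"behind"`.
#'
#' @param cam a [camera_model()].
#' @param p world point (length-3 numeric).
#' @return Numeric `(u, v)` in pixels, or the character sentinel `"behind"`.
#' @export
project_point <- function(cam, p) {
  pc <- drop(to_camera(cam, p))
  if (pc[3] <= 0) return("behind")
  cam$principal_point + cam$focal_px * pc[1:2] / pc[3]
}

# vectorised projection: n x 3 world points -> list(uv = n x 2, z = n)
# (rows with z <= 0 have uv = NA)
project_points <- function(cam, p) {
  pc <- to_camera(cam, p)
  z <- pc[, 3]
  uv <- cbind(cam$principal_point[1] + cam$focal_px * pc[, 1] / z,
              cam$principal_point[2] + cam$focal_px * pc[, 2] / z)
  uv[z <= 0, ] <- NA_real_
  list(uv = uv, z = z)
}

#' Wheat-head geometry
#'
#' A head is modelled as an ellipsoid of revolution: semi-axis `length/2`
#' along `axis`, semi-axes `radius` across it, attached at `anchor` (the tip
#' of its stem) and extending along `axis`.
#'
#' @param anchor attachment point (length-3 world coordinates).
#' @param axis unit direction of the head.
#' @param length head length in world units (> 0).
#' @param radius head radius in world units (> 0).
#' @return An object of class `head_geometry`.
#' @export
head_geometry <- function(anchor, axis, length = 0.14, radius = 0.04) {
  if (!is_scalar_num(length) || length <= 0) stopf("head length must be > 0")
  if (!is_scalar_num(radius) || radius <= 0) stopf("head radius must be > 0")
  structure(list(anchor = as.numeric(anchor), axis = unit3(as.numeric(axis)),
                 length = length, radius = radius),
            class = "head_geometry")
}

# orthonormal frame with 3rd column = axis
axis_frame <- function(axis) {
  a <- unit3(axis)
  helper <- if (abs(a[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- unit3(pracma_cross(helper, a))
  e2 <- pracma_cross(a, e1)
  cbind(e1, e2, a)
}

# quasi-uniform points on the unit sphere (Fibonacci spiral)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# n x 3 world points on the head's ellipsoid surface
head_surface_points <- function(head, n = 64L) {
  u <- fibonacci_sphere(n)
  fr <- axis_frame(head$axis)
  centre <- head$anchor + head$axis * head$length / 2
  local <- u %*% diag(c(head$radius, head$radius, head$length / 2))
  sweep(local %*% t(fr), 2L, centre, `+`)
}

#' Bounding box in pixel coordinates
#'
#' Continuous, 0-based, origin top-left; `x_min < x_max`, `y_min < y_max`.
#'
#' @param x_min,y_min,x_max,y_max box edges in pixels.
#' @return An object of class `bbox` (named numeric of length 4).
#' @export
bbox <- function(x_min, y_min, x_max, y_max) {
  if (!(x_min < x_max && y_min < y_max))
    stopf("invalid bbox: need x_min < x_max and y_min < y_max")
  structure(c(x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max),
            class = "bbox")
}

bbox_width <- function(b) b[["x_max"]] - b[["x_min"]]
bbox_height <- function(b) b[["y_max"]] - b[["y_min"]]
bbox_area <- function(b) bbox_width(b) * bbox_height(b)
bbox_center <- function(b) {
  c((b[["x_min"]] + b[["x_max"]]) / 2, (b[["y_min"]] + b[["y_max"]]) / 2)
}

#' Project a head to its image bounding box
#'
#' Samples `n_samples` points on the head's ellipsoid surface, projects them,
#' and takes the axis-aligned min/max, clipped to the frame. The box is
#' dropped (returns `NULL`) when fewer than `min_visible_frac` of the sample
#' points are visible — inside the frame, in front of the camera and, when an
#' `id_buffer` from [render_scene()] is supplied, not covered by a different
#' head.
#'
#' @param cam a [camera_model()].
#' @param head a [head_geometry()].
#' @param n_samples number of surface sample points (>= 16).
#' @param min_visible_frac minimum visible fraction to keep the box.
#' @param id_buffer optional integer matrix (height x width) of head ids from
#'   the renderer; used to discount occluded sample points.
#' @param head_id id of this head within `id_buffer`.
#' @return A [bbox()] clipped to the frame, or `NULL`.
#' @export
compute_bbox <- function(cam, head, n_samples = 64L, min_visible_frac = 0.25,
                         id_buffer = NULL, head_id = NULL) {
  stopifnot(inherits(head, "head_geometry"))
  if (n_samples < 16L) stopf("n_samples must be >= 16")
  pts <- head_surface_points(head, n_samples)
  pr <- project_points(cam, pts)
  front <- pr$z > 0
  if (!any(front)) return(NULL)
  uv <- pr$uv[front, , drop = FALSE]
  in_frame <- uv[, 1] >= 0 & uv[, 1] <= cam$width &
    uv[, 2] >= 0 & uv[, 2] <= cam$height
  visible <- in_frame
  if (!is.null(id_buffer) && !is.null(head_id)) {
    px <- clamp(floor(uv[, 1]) + 1L, 1L, ncol(id_buffer))
    py <- clamp(floor(uv[, 2]) + 1L, 1L, nrow(id_buffer))
    ids <- id_buffer[cbind(py, px)]
    visible <- visible & (ids == head_id | ids == 0L)
  }
  if (sum(visible) / n_samples < min_visible_frac) return(NULL)
  x0 <- max(0, min(uv[, 1]))
  x1 <- min(cam$width, max(uv[, 1]))
  y0 <- max(0, min(uv[, 2]))
  y1 <- min(cam$height, max(uv[, 2]))
  if (!(x0 < x1 && y0 < y1)) return(NULL)
  bbox(x0, y0, x1, y1)
}
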