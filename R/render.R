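# Procedural rasteriser. This is a deliberately simple CPU renderer that
# honours the geometric contract of the scene: heads are ray-cast ellipsoids
# (exact footprints, giving an id-buffer and depth-consistent occlusion),
# stems are projected polylines, and the ground is a seeded noise texture
# with foliage blobs. It makes no attempt at photo-realism; its job is to
# give the translation and detection stages images whose head footprints
# agree with the annotations.

#' Rendering style
#'
#' Colour palette and texture parameters. Two presets emulate a two-domain
#' setting for translation experiments: `"synthetic"` (flat golden heads on
#' brown soil) and `"field"` (brighter, cooler, higher-contrast scenes that
#' play the role of the real domain in tests).
#'
#' @param preset `"synthetic"` or `"field"`.
#' @param head,stem,soil,foliage RGB triples in `[0, 1]` overriding the
#'   preset.
#' @param noise_amp amplitude of the background value noise.
#' @param contrast global contrast multiplier applied around mid-grey.
#' @return An object of class `render_style`.
#' @export
render_style <- function(preset = c("synthetic", "field"),
                         head = NULL, stem = NULL, soil = NULL,
                         foliage = NULL, noise_amp = NULL, contrast = NULL) {
  preset <- match.arg(preset)
  p <- if (preset == "synthetic") {
    list(head = c(0.85, 0.74, 0.34), stem = c(0.30, 0.45, 0.18),
         soil = c(0.36, 0.28, 0.20), foliage = c(0.20, 0.33, 0.14),
         noise_amp = 0.05, contrast = 1.0)
  } else {
    list(head = c(0.93, 0.88, 0.55), stem = c(0.25, 0.52, 0.28),
         soil = c(0.30, 0.34, 0.28), foliage = c(0.16, 0.40, 0.22),
         noise_amp = 0.09, contrast = 1.25)
  }
  p$head <- head %||% p$head
  p$stem <- stem %||% p$stem
  p$soil <- soil %||% p$soil
  p$foliage <- foliage %||% p$foliage
  p$noise_amp <- noise_amp %||% p$noise_amp
  p$contrast <- contrast %||% p$contrast
  structure(p, class = "render_style")
}

# seeded smooth value noise (coarse Gaussian grid upsampled bilinearly)
smooth_noise <- function(h, w, cells = 12L) {
  coarse <- matrix(stats::rnorm(cells * cells), cells, cells)
  as.matrix(EBImage::resize(EBImage::Image(coarse), w = h, h = w))
}

#' Render a scene to an RGB image
#'
#' Draws, in order: the textured ground plus foliage blobs, the projected
#' stem polylines, then the heads far-to-near as ray-cast ellipsoids with a
#' Lambertian-ish shade and spikelet noise. Deterministic given `seed`.
#'
#' @param scene a [wheat_scene()].
#' @param cam a [camera_model()].
#' @param style a [render_style()].
#' @param seed seed for the texture noise; defaults to the scene's seed.
#' @return List of class `wheat_render`: `image` (height x width x 3 array in
#'   `[0, 1]`), `id_buffer` (integer matrix, 0 = background, i = head i) and
#'   `depth` (camera-space depth of the drawn head surface).
#' @export
render_scene <- function(scene, cam, style = render_style(), seed = NULL) {
  stopifnot(inherits(scene, "wheat_scene"), inherits(cam, "camera_model"))
  seed <- seed %||% scene$spec$seed
  with_seed(seed, {
    h <- cam$height
    w <- cam$width
    img <- array(0, c(h, w, 3))
    n1 <- smooth_noise(h, w, 10L)
    n2 <- smooth_noise(h, w, 28L)
    tex <- style$noise_amp * (0.7 * n1 + 0.3 * n2)
    for (c3 in 1:3) img[, , c3] <- style$soil[c3] + tex
    # foliage blobs: soft discs of darker green on the ground
    n_blobs <- round(40 * scene$spec$background_density)
    if (n_blobs > 0) {
      bx <- stats::runif(n_blobs, 0, w)
      by <- stats::runif(n_blobs, 0, h)
      br <- stats::runif(n_blobs, 0.02, 0.06) * w
      xs <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
      ys <- matrix(rep(seq_len(h) - 0.5, times = w), h, w)
      for (k in seq_len(n_blobs)) {
        d2 <- (xs - bx[k])^2 + (ys - by[k])^2
        a <- exp(-d2 / (2 * (br[k] / 2)^2)) * 0.8
        for (c3 in 1:3)
          img[, , c3] <- (1 - a) * img[, , c3] + a * style$foliage[c3]
      }
    }
    id_buf <- matrix(0L, h, w)
    depth <- matrix(Inf, h, w)
    # stems: sample each polyline densely and stamp pixels
    for (st in scene$stems) {
      poly <- st$polyline
      pr <- project_points(cam, poly)
      uv <- pr$uv
      ok <- which(pr$z > 0)
      if (length(ok) < 2) next
      for (j in seq_len(length(ok) - 1L)) {
        a <- uv[ok[j], ]
        b <- uv[ok[j + 1L], ]
        if (anyNA(a) || anyNA(b)) next
        nstep <- max(2L, ceiling(max(abs(b - a))) + 1L)
        t <- seq(0, 1, length.out = nstep)
        px <- floor(a[1] + t * (b[1] - a[1])) + 1L
        py <- floor(a[2] + t * (b[2] - a[2])) + 1L
        keep <- px >= 1 & px <= w & py >= 1 & py <= h
        if (!any(keep)) next
        idx <- cbind(py[keep], px[keep])
        shade <- stats::runif(1, 0.85, 1.1)
        for (c3 in 1:3) {
          ch <- img[, , c3]
          ch[idx] <- style$stem[c3] * shade
          img[, , c3] <- ch
        }
      }
    }
    # heads, far to near, ray-cast over each head's pixel bbox
    centres <- t(vapply(scene$heads, function(hd)
      hd$anchor + hd$axis * hd$length / 2, numeric(3)))
    zc <- to_camera(cam, centres)[, 3]
    ord <- order(-zc)
    for (i in ord) {
      hd <- scene$heads[[i]]
      hit <- raycast_ellipsoid(cam, hd)
      if (is.null(hit)) next
      sub <- hit$mask
      if (!any(sub)) next
      rows <- hit$rows
      cols <- hit$cols
      idx <- cbind(rows[sub], cols[sub])
      zh <- hit$z[sub]
      closer <- zh < depth[idx]
      if (!any(closer)) next
      idx <- idx[closer, , drop = FALSE]
      zh <- zh[closer]
      depth[idx] <- zh
      id_buf[idx] <- i
      shade <- hit$shade[sub][closer]
      spik <- 1 + 0.25 * sin(idx[, 1] * 1.7 + idx[, 2] * 0.9 + i) *
        stats::runif(1, 0.5, 1)
      for (c3 in 1:3) {
        ch <- img[, , c3]
        ch[idx] <- clamp(style$head[c3] * shade * spik, 0, 1)
        img[, , c3] <- ch
      }
    }
    img <- clamp(0.5 + style$contrast * (img - 0.5), 0, 1)
    structure(list(image = img, id_buffer = id_buf, depth = depth),
              class = "wheat_render")
  })
}

# ray-cast one ellipsoid head over its projected pixel bounding region;
# returns per-pixel hit mask, depth and a simple shade term
raycast_ellipsoid <- function(cam, head) {
  b <- compute_bbox(cam, head, min_visible_frac = 1e-9)
  if (is.null(b)) return(NULL)
  x0 <- max(1L, floor(b[["x_min"]]) + 1L)
  x1 <- min(cam$width, ceiling(b[["x_max"]]))
  y0 <- max(1L, floor(b[["y_min"]]) + 1L)
  y1 <- min(cam$height, ceiling(b[["y_max"]]))
  if (x1 < x0 || y1 < y0) return(NULL)
  u <- (rep(x0:x1, each = y1 - y0 + 1L)) - 0.5
  v <- (rep(y0:y1, times = x1 - x0 + 1L)) - 0.5
  rows <- rep(y0:y1, times = x1 - x0 + 1L)
  cols <- rep(x0:x1, each = y1 - y0 + 1L)
  # ray directions in world coords: rot' %*% (xn, yn, 1)
  xn <- (u - cam$principal_point[1]) / cam$focal_px
  yn <- (v - cam$principal_point[2]) / cam$focal_px
  dirs <- cbind(xn, yn, 1) %*% cam$rot # n x 3 world directions
  # transform to ellipsoid frame and scale to unit sphere
  fr <- axis_frame(head$axis)
  centre <- head$anchor + head$axis * head$length / 2
  scl <- c(head$radius, head$radius, head$length / 2)
  o_loc <- drop((cam$position - centre) %*% fr) / scl
  d_loc <- sweep(dirs %*% fr, 2L, scl, `/`)
  a <- rowSums(d_loc^2)
  bq <- 2 * (d_loc %*% o_loc)[, 1]
  cq <- sum(o_loc^2) - 1
  disc <- bq^2 - 4 * a * cq
  mask <- disc >= 0
  t_hit <- rep(NA_real_, length(a))
  t_hit[mask] <- (-bq[mask] - sqrt(disc[mask])) / (2 * a[mask])
  mask <- mask & !is.na(t_hit) & t_hit > 0
  # camera-space depth of the hit: z = t (dirs have unit forward component)
  z <- t_hit
  # shade from surface normal vs vertical
  shade <- rep(1, length(a))
  if (any(mask)) {
    p_loc <- o_loc_matrix(o_loc, d_loc, t_hit, mask)
    nz <- abs(p_loc[, 3])
    shade[mask] <- 0.75 + 0.35 * nz[mask]
  }
  list(rows = rows, cols = cols, mask = mask, z = z, shade = shade)
}

o_loc_matrix <- function(o_loc, d_loc, t_hit, mask) {
  p <- matrix(NA_real_, nrow(d_loc), 3)
  p[mask, ] <- sweep(d_loc[mask, , drop = FALSE] * t_hit[mask], 2L, o_loc, `+`)
  p
}
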