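# Appearance-based partitioning of the target domain: deep-style image
# features + K-means with k-means++ seeding. The feature extractor is
# pluggable; the package default is a deterministic channel-wise colour
# histogram (16 bins per RGB channel, 48 dimensions), which captures the
# global appearance modes (lighting, maturity, soil colour) that the
# clustering step separates. A pooled pretrained-CNN extractor can be
# supplied through the same contract.

#' Channel-wise colour-histogram feature extractor
#'
#' @param bins_per_channel histogram bins per RGB channel.
#' @return A function mapping an `H x W x 3` array in `[0, 1]` to a numeric
#'   feature vector of length `3 * bins_per_channel` (bin proportions).
#' @export
feature_extractor_histogram <- function(bins_per_channel = 16L) {
  force(bins_per_channel)
  function(img) {
    if (length(dim(img)) != 3L || dim(img)[3] < 3L)
      stopf("expected an H x W x 3 image array")
    f <- lapply(1:3, function(c3) {
      v <- clamp(as.numeric(img[, , c3]), 0, 1)
      bin <- pmin(floor(v * bins_per_channel) + 1L, bins_per_channel)
      h <- tabulate(bin, bins_per_channel)
      h / sum(h)
    })
    unlist(f, use.names = FALSE)
  }
}

#' Extract a feature matrix from a set of images
#'
#' @param images named list of image arrays, or a character vector of PNG
#'   paths (names default to file names).
#' @param extractor feature function; default
#'   [feature_extractor_histogram()]. Any function image -> numeric vector
#'   (e.g. pooled activations of a pretrained network) can be plugged in.
#' @param l2_normalize L2-normalise each feature row (stabilises scale across
#'   extractors before K-means).
#' @return A `feature_matrix`: numeric matrix with rownames = image ids.
#' @export
extract_features <- function(images, extractor = feature_extractor_histogram(),
                             l2_normalize = TRUE) {
  if (is.character(images)) {
    paths <- images
    ids <- names(paths) %||% sub("\\.png$", "", basename(paths))
    images <- lapply(paths, function(p) {
      img <- tryCatch(png::readPNG(p),
                      error = function(e) stopf("unreadable image: %s", p))
      img
    })
    names(images) <- ids
  }
  if (is.null(names(images)))
    names(images) <- sprintf("img_%04d", seq_along(images))
  rows <- lapply(images, extractor)
  dim_f <- length(rows[[1]])
  mat <- do.call(rbind, rows)
  if (!all(is.finite(mat))) stopf("non-finite feature values")
  if (l2_normalize) {
    nrm <- sqrt(rowSums(mat^2))
    nrm[nrm == 0] <- 1
    mat <- mat / nrm
  }
  rownames(mat) <- names(images)
  structure(mat, class = c("feature_matrix", class(mat)), dim_f = dim_f)
}

# k-means++ initial centres (Arthur & Vassilvitskii seeding)
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centres <- matrix(0, k, ncol(x))
  first <- sample.int(n, 1L)
  centres[1L, ] <- x[first, ]
  d2 <- rowSums((x - matrix(centres[1L, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L)) {
    if (all(d2 == 0)) {
      pick <- sample.int(n, 1L)
    } else {
      pick <- sample.int(n, 1L, prob = d2)
    }
    centres[j + 1L, ] <- x[pick, ]
    d2_new <- rowSums((x - matrix(x[pick, ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, d2_new)
  }
  centres
}

# squared distances n x k
dist2_to_centres <- function(x, centres) {
  xx <- rowSums(x^2)
  cc <- rowSums(centres^2)
  outer(xx, cc, `+`) - 2 * x %*% t(centres)
}

lloyd_once <- function(x, k, max_iter, tol = 1e-10) {
  centres <- kmeanspp_init(x, k)
  n <- nrow(x)
  inertia_trace <- numeric(0)
  assign_vec <- integer(n)
  for (it in seq_len(max_iter)) {
    d2 <- dist2_to_centres(x, centres)
    assign_vec <- max.col(-d2, ties.method = "first")
    inertia <- sum(d2[cbind(seq_len(n), assign_vec)])
    inertia_trace <- c(inertia_trace, inertia)
    # rescue empty clusters: re-seed at the point farthest from its centre
    for (j in seq_len(k)) {
      if (!any(assign_vec == j)) {
        own_d2 <- d2[cbind(seq_len(n), assign_vec)]
        far <- which.max(own_d2)
        centres[j, ] <- x[far, ]
        assign_vec[far] <- j
      }
    }
    new_centres <- centres
    for (j in seq_len(k)) {
      new_centres[j, ] <- colMeans(x[assign_vec == j, , drop = FALSE])
    }
    if (max(abs(new_centres - centres)) < tol) {
      centres <- new_centres
      break
    }
    centres <- new_centres
  }
  d2 <- dist2_to_centres(x, centres)
  assign_vec <- max.col(-d2, ties.method = "first")
  inertia <- sum(d2[cbind(seq_len(n), assign_vec)])
  list(centres = centres, assignments = assign_vec, inertia = inertia,
       inertia_trace = c(inertia_trace, inertia))
}

#' Fit K-means on image features
#'
#' Lloyd's algorithm with k-means++ initialisation, best of `n_init` restarts
#' by inertia. Empty clusters are rescued by re-seeding the centre at the
#' point farthest from its current centre, keeping `k` fixed. Deterministic
#' given `seed`.
#'
#' @param features a [extract_features()] matrix (rownames = image ids).
#' @param k number of clusters; the published configuration uses 4, balancing
#'   cluster count against per-cluster image volume.
#' @param seed RNG seed.
#' @param n_init number of restarts.
#' @param max_iter Lloyd iteration cap per restart.
#' @param min_cluster_warn warn when any cluster ends up smaller than this
#'   (small translation targets starve adversarial training).
#' @return An object of class `cluster_model`: `k`, `centroids`,
#'   `assignments` (named integer vector, 0-based cluster indices keyed by
#'   image id), `inertia`, `inertia_trace` (best restart), `seed`.
#' @export
fit_kmeans <- function(features, k = 4L, seed = 1L, n_init = 10L,
                       max_iter = 100L, min_cluster_warn = 100L) {
  x <- unclass(features)
  n <- nrow(x)
  if (k < 1L) stopf("k must be >= 1")
  if (k > n) stopf("k (%d) exceeds the number of images (%d)", k, n)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_init)) {
      fit <- lloyd_once(x, k, max_iter)
      if (is.null(best) || fit$inertia < best$inertia) best <- fit
    }
  })
  if (any(tabulate(best$assignments, k) == 0L))
    stopf("empty cluster after fitting")
  sizes <- tabulate(best$assignments, k)
  if (any(sizes < min_cluster_warn))
    warning(sprintf(
      "cluster sizes %s fall below %d images; adversarial training on very small targets is unreliable",
      paste(sizes[sizes < min_cluster_warn], collapse = ", "),
      min_cluster_warn), call. = FALSE)
  assignments <- best$assignments - 1L
  names(assignments) <- rownames(x)
  structure(
    list(k = as.integer(k), centroids = best$centres,
         assignments = assignments, inertia = best$inertia,
         inertia_trace = best$inertia_trace, seed = as.integer(seed)),
    class = "cluster_model")
}

#' Partition a dataset by a fitted cluster model
#'
#' Splits a [dataset_bundle()] into `k` disjoint sub-bundles covering the
#' input; images, annotations and heatmaps travel together.
#'
#' @param dataset a [dataset_bundle()].
#' @param model a [fit_kmeans()] model covering every image id.
#' @return List of `k` bundles, element `j` holding cluster index `j - 1`.
#' @export
partition_dataset <- function(dataset, model) {
  stopifnot(inherits(model, "cluster_model"))
  ids <- dataset_ids(dataset)
  missing <- setdiff(ids, names(model$assignments))
  if (length(missing))
    stopf("ids missing from cluster assignments: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  lapply(seq_len(model$k) - 1L, function(cl) {
    keep <- ids[model$assignments[ids] == cl]
    subset_bundle(dataset, keep, name = sprintf("%s_c%d", dataset$name, cl))
  })
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 = identical clusterings, 0 = chance-level agreement.
#'
#' @param a,b integer label vectors of equal length.
#' @return Scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

#' Save / load cluster assignments as JSON
#'
#' The JSON maps cluster index (as a string) to the list of image ids.
#' @param model a `cluster_model`.
#' @param path JSON file.
#' @export
write_clusters_json <- function(model, path) {
  by_cluster <- split(names(model$assignments), model$assignments)
  jsonlite::write_json(by_cluster, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}
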