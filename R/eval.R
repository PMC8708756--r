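# Detection scoring: confidence filtering, greedy IoU matching, and the two
# headline metrics — mean IoU (+/- SD over images) and mean Euclidean
# distance between matched box centres.

#' Intersection over union of two boxes
#'
#' @param a,b [bbox()] objects (continuous coordinates).
#' @return Scalar in `[0, 1]`; 0 when disjoint.
#' @export
iou <- function(a, b) {
  ix <- min(a[["x_max"]], b[["x_max"]]) - max(a[["x_min"]], b[["x_min"]])
  iy <- min(a[["y_max"]], b[["y_max"]]) - max(a[["y_min"]], b[["y_min"]])
  if (ix <= 0 || iy <= 0) return(0)
  inter <- ix * iy
  inter / (bbox_area(a) + bbox_area(b) - inter)
}

#' Euclidean distance between box centres
#'
#' @param a,b [bbox()] objects.
#' @return Distance in pixels.
#' @export
center_distance <- function(a, b) {
  sqrt(sum((bbox_center(a) - bbox_center(b))^2))
}

#' A detection: box plus confidence
#'
#' @param box a [bbox()].
#' @param confidence scalar in `[0, 1]`.
#' @export
detection <- function(box, confidence) {
  stopifnot(inherits(box, "bbox"))
  if (confidence < 0 || confidence > 1) stopf("confidence must be in [0, 1]")
  structure(list(box = box, confidence = confidence), class = "detection")
}

#' Filter detections by confidence
#'
#' Keeps detections with `confidence >= threshold` (inclusive), preserving
#' order. The published protocol scores at threshold 0.7, with 0.4 examined
#' for models trained without real images.
#'
#' @param dets list of [detection()].
#' @param threshold scalar in `[0, 1]`.
#' @export
filter_detections <- function(dets, threshold) {
  if (threshold < 0 || threshold > 1) stopf("threshold must be in [0, 1]")
  dets[vapply(dets, function(d) d$confidence >= threshold, logical(1))]
}

#' Greedy one-to-one box matching by descending IoU
#'
#' Repeatedly takes the remaining (prediction, ground-truth) pair of highest
#' IoU > 0; ties broken by lower prediction index, then lower ground-truth
#' index.
#'
#' @param preds,gts lists of [bbox()].
#' @return List with `pairs` (data frame `pred`, `gt`, `iou`; 1-based
#'   indices), `unmatched_preds`, `unmatched_gts`.
#' @export
match_boxes <- function(preds, gts) {
  np <- length(preds)
  ng <- length(gts)
  pairs <- data.frame(pred = integer(0), gt = integer(0), iou = numeric(0))
  if (np && ng) {
    m <- matrix(0, np, ng)
    for (i in seq_len(np)) for (j in seq_len(ng))
      m[i, j] <- iou(preds[[i]], gts[[j]])
    repeat {
      best <- max(m)
      if (best <= 0) break
      hit <- which(m == best, arr.ind = TRUE)
      hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE][1, ]
      pairs <- rbind(pairs, data.frame(pred = hit[[1]], gt = hit[[2]],
                                       iou = best))
      m[hit[[1]], ] <- -1
      m[, hit[[2]]] <- -1
    }
  }
  list(pairs = pairs,
       unmatched_preds = setdiff(seq_len(np), pairs$pred),
       unmatched_gts = setdiff(seq_len(ng), pairs$gt))
}

#' Score one image
#'
#' After confidence filtering and greedy matching, the per-image IoU is
#' `sum(matched IoUs) / (n_matched + n_unmatched_gt + n_unmatched_pred)`
#' (`aggregation = "penalize_unmatched"`, the default — both missed heads and
#' hallucinated detections count as IoU 0), or the mean over matched pairs
#' only (`"matched_only"`). Centre distances are collected over matched pairs
#' only. An image with no ground truth and no surviving detections scores
#' IoU 1 (vacuous agreement).
#'
#' @param preds list of [detection()].
#' @param gts list of [bbox()].
#' @param threshold confidence threshold.
#' @param aggregation `"penalize_unmatched"` or `"matched_only"`.
#' @return List: `iou` (per-image score), `distances` (matched centre
#'   distances), `n_matched`, `n_missed`, `n_spurious`.
#' @export
image_score <- function(preds, gts, threshold = 0.7,
                        aggregation = c("penalize_unmatched", "matched_only")) {
  aggregation <- match.arg(aggregation)
  kept <- filter_detections(preds, threshold)
  boxes <- lapply(kept, `[[`, "box")
  mr <- match_boxes(boxes, gts)
  n_m <- nrow(mr$pairs)
  n_miss <- length(mr$unmatched_gts)
  n_spur <- length(mr$unmatched_preds)
  if (n_m + n_miss + n_spur == 0L) {
    img_iou <- 1
  } else if (aggregation == "penalize_unmatched") {
    img_iou <- sum(mr$pairs$iou) / (n_m + n_miss + n_spur)
  } else {
    img_iou <- if (n_m) mean(mr$pairs$iou) else 0
  }
  distances <- if (n_m) {
    vapply(seq_len(n_m), function(r)
      center_distance(boxes[[mr$pairs$pred[r]]], gts[[mr$pairs$gt[r]]]),
      numeric(1))
  } else numeric(0)
  list(iou = img_iou, distances = distances, n_matched = n_m,
       n_missed = n_miss, n_spurious = n_spur)
}

#' Evaluate a detection run
#'
#' @param per_image named list: each element is `list(preds = , gts = )` with
#'   `preds` a list of [detection()] and `gts` a list of [bbox()].
#' @param threshold confidence threshold.
#' @param aggregation see [image_score()].
#' @return An `eval_report`: `mean_iou`, `sd_iou` (population SD over
#'   per-image scores), `mean_euclid` (mean over all matched centre
#'   distances in the set; `NaN` when nothing matched), `per_image` (data
#'   frame of per-image scores for boxplot-style inspection).
#' @export
evaluate_detections <- function(per_image, threshold = 0.7,
                                aggregation = "penalize_unmatched") {
  if (!length(per_image)) stopf("need at least one image to evaluate")
  scores <- lapply(per_image, function(x)
    image_score(x$preds, x$gts, threshold, aggregation))
  ious <- vapply(scores, `[[`, numeric(1), "iou")
  dists <- unlist(lapply(scores, `[[`, "distances"))
  per_df <- data.frame(
    image_id = names(per_image) %||% as.character(seq_along(per_image)),
    iou = ious,
    n_matched = vapply(scores, `[[`, numeric(1), "n_matched"),
    n_missed = vapply(scores, `[[`, numeric(1), "n_missed"),
    n_spurious = vapply(scores, `[[`, numeric(1), "n_spurious"),
    row.names = NULL)
  structure(
    list(mean_iou = mean(ious),
         sd_iou = sqrt(mean((ious - mean(ious))^2)),
         mean_euclid = if (length(dists)) mean(dists) else NaN,
         per_image = per_df,
         threshold = threshold, aggregation = aggregation),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Detection evaluation over %d images (threshold %.2f)\n",
              nrow(x$per_image), x$threshold))
  cat(sprintf("  Mean IoU            : %.4f +/- %.4f\n", x$mean_iou, x$sd_iou))
  cat(sprintf("  Mean Euclidean dist : %.4f px\n", x$mean_euclid))
  invisible(x)
}

#' Reference blob detector
#'
#' A deliberately simple stand-in for a learned detector so the full
#' generate-translate-evaluate loop can be exercised end to end: head-like
#' pixels are found by a colour saliency score (`R + G - 2B`, high for golden
#' heads, low for soil and foliage), thresholded, labelled into connected
#' components, and each component of sufficient area becomes one detection
#' with confidence equal to its normalised mean saliency. Detections are
#' returned sorted by descending confidence.
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param saliency_threshold threshold on the saliency score.
#' @param min_area minimum component area in pixels.
#' @return List of [detection()], sorted by descending confidence.
#' @export
reference_blob_detector <- function(image, saliency_threshold = 0.62,
                                    min_area = 6L) {
  s <- image[, , 1] + image[, , 2] - 2 * image[, , 3]
  mask <- s > saliency_threshold
  if (!any(mask)) return(list())
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- as.matrix(lab)
  n_comp <- max(lab)
  dets <- list()
  for (k in seq_len(n_comp)) {
    idx <- which(lab == k, arr.ind = TRUE)
    if (nrow(idx) < min_area) next
    # rows are y (1-based), cols are x; convert to continuous 0-based edges
    x0 <- min(idx[, 2]) - 1
    x1 <- max(idx[, 2])
    y0 <- min(idx[, 1]) - 1
    y1 <- max(idx[, 1])
    sal <- mean(s[idx])
    dets[[length(dets) + 1L]] <- list(box = bbox(x0, y0, x1, y1), sal = sal)
  }
  if (!length(dets)) return(list())
  sals <- vapply(dets, `[[`, numeric(1), "sal")
  conf <- sals / max(sals)
  ord <- order(-conf)
  lapply(ord, function(i) detection(dets[[i]]$box, conf[i]))
}

#' Read detections from CSV
#'
#' Expects header `image_id,x_min,y_min,x_max,y_max,confidence`; any external
#' detector's output can be scored through this adapter.
#'
#' @param path CSV file.
#' @return Named list (by image id) of lists of [detection()].
#' @export
read_detections_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "x_min", "y_min", "x_max", "y_max", "confidence")
  if (!all(need %in% names(df)))
    stopf("detections CSV must have columns: %s", paste(need, collapse = ","))
  out <- list()
  for (i in seq_len(nrow(df))) {
    id <- as.character(df$image_id[i])
    d <- detection(bbox(df$x_min[i], df$y_min[i], df$x_max[i], df$y_max[i]),
                   df$confidence[i])
    out[[id]] <- c(out[[id]], list(d))
  }
  out
}

#' Write an evaluation report to JSON
#'
#' @param report an `eval_report`.
#' @param path JSON file; includes the per-image scores.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(
    list(mean_iou = report$mean_iou, sd_iou = report$sd_iou,
         mean_euclid = report$mean_euclid, threshold = report$threshold,
         aggregation = report$aggregation, per_image = report$per_image),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
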