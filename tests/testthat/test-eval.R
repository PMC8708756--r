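test_that("IoU matches hand computations and basic identities", {
  a <- bbox(0, 0, 2, 2)
  expect_equal(iou(a, a), 1.0)
  expect_equal(iou(a, bbox(5, 5, 7, 7)), 0.0)
  # intersection 2, union 6
  expect_equal(iou(a, bbox(1, 0, 3, 2)), 1 / 3, tolerance = 1e-12)

  set.seed(31)
  for (i in 1:200) {
    p <- list(a = random_bbox(), b = random_bbox())
    v <- iou(p$a, p$b)
    expect_gte(v, 0)
    expect_lte(v, 1)
    expect_equal(v, iou(p$b, p$a), tolerance = 1e-12)
  }
})

test_that("IoU agrees with a stratified pixel-membership oracle", {
  set.seed(97)
  errs <- vapply(1:100, function(i) {
    p <- if (i %% 2 == 0) overlapping_bbox_pair()
         else list(a = random_bbox(), b = random_bbox())
    abs(iou(p$a, p$b) - mc_iou(p$a, p$b, n = 1e6))
  }, numeric(1))
  expect_lt(max(errs), 1e-3)
})

test_that("centre distance is Euclidean and translation-invariant", {
  a <- bbox(-1, -1, 1, 1)            # centre (0, 0)
  b <- bbox(2, 3, 4, 5)              # centre (3, 4)
  expect_equal(center_distance(a, a), 0.0)
  expect_equal(center_distance(a, b), 5.0)
  shift <- function(x, d) bbox(x[["x_min"]] + d, x[["y_min"]] + d,
                               x[["x_max"]] + d, x[["y_max"]] + d)
  expect_equal(center_distance(shift(a, 7.3), shift(b, 7.3)), 5.0,
               tolerance = 1e-12)
})

test_that("confidence filtering is inclusive and order-preserving", {
  dets <- lapply(c(0.6, 0.7, 0.9), function(cf)
    detection(bbox(0, 0, 1, 1), cf))
  expect_length(filter_detections(dets, 0), 3)
  kept <- filter_detections(dets, 0.7)
  expect_length(kept, 2)
  expect_equal(vapply(kept, `[[`, numeric(1), "confidence"), c(0.7, 0.9))
  expect_length(filter_detections(dets, 1.0), 0)
})

test_that("greedy matching is one-to-one and optimal on small instances", {
  gts <- list(bbox(0, 0, 10, 10), bbox(20, 0, 30, 10))
  mr <- match_boxes(gts, gts)
  expect_equal(nrow(mr$pairs), 2)
  expect_equal(mr$pairs$iou, c(1, 1))
  expect_length(mr$unmatched_preds, 0)

  mr0 <- match_boxes(list(), gts)
  expect_equal(mr0$unmatched_gts, 1:2)

  # the spec'd cross-overlap case: greedy picks (p0,g0) then (p1,g1)
  p0 <- bbox(0, 0, 10, 10)
  g0 <- bbox(0, 0, 10, 13.34)   # iou(p0,g0) ~ 0.75 > others
  g1 <- bbox(2, 0, 12, 10)
  p1 <- bbox(5, 0, 15, 10)
  mr2 <- match_boxes(list(p0, p1), list(g0, g1))
  expect_equal(mr2$pairs$pred, c(1, 2))
  expect_equal(mr2$pairs$gt, c(1, 2))

  # brute-force assignment oracle agrees with greedy on random instances
  set.seed(13)
  for (i in 1:30) {
    preds <- replicate(sample(0:4, 1), random_bbox(40, 40, 5),
                       simplify = FALSE)
    gts_r <- replicate(sample(1:4, 1), random_bbox(40, 40, 5),
                       simplify = FALSE)
    mr <- match_boxes(preds, gts_r)
    # one-to-one, positive-IoU pairs only
    expect_equal(anyDuplicated(mr$pairs$pred), 0)
    expect_equal(anyDuplicated(mr$pairs$gt), 0)
    if (nrow(mr$pairs)) expect_true(all(mr$pairs$iou > 0))
    bf <- brute_force_match(preds, gts_r)
    if (!is.null(bf$pairs)) {
      # greedy weighted matching is a 1/2-approximation of the optimum and
      # never exceeds it
      expect_lte(sum(mr$pairs$iou), bf$score + 1e-12)
      expect_gte(sum(mr$pairs$iou), 0.5 * bf$score)
      # greedy's first pair is the globally best-IoU pair
      if (nrow(mr$pairs))
        expect_equal(mr$pairs$iou[1], max(bf_iou_matrix(preds, gts_r)))
    }
  }
})

test_that("per-image scoring follows the declared aggregation", {
  gts <- list(bbox(0, 0, 10, 10), bbox(30, 30, 40, 40))
  perfect <- lapply(gts, detection, confidence = 1)
  sc <- image_score(perfect, gts, 0.7)
  expect_equal(sc$iou, 1.0)
  expect_equal(sc$distances, c(0, 0))

  none <- image_score(list(), gts, 0.7)
  expect_equal(none$iou, 0.0)

  # one matched pair with iou 0.5 plus one unmatched gt: 0.5 / 2
  half <- list(detection(bbox(0, 0, 10, 5), 0.9))  # iou vs gt1 = 0.5
  sc2 <- image_score(half, gts, 0.7)
  expect_equal(sc2$iou, 0.25, tolerance = 1e-12)

  # vacuous truth: nothing to find, nothing found
  expect_equal(image_score(list(), list(), 0.7)$iou, 1.0)

  # matched-only aggregation ignores the unmatched gt
  sc3 <- image_score(half, gts, 0.7, aggregation = "matched_only")
  expect_equal(sc3$iou, 0.5, tolerance = 1e-12)
})

test_that("evaluation aggregates with population SD and is permutation-invariant", {
  # craft per-image scores exactly: pred (0,0,10,h) inside gt (0,0,10,10)
  # has iou = h/10
  g <- bbox(0, 0, 10, 10)
  h_for <- function(v) 10 * v
  per <- list(
    img1 = list(preds = list(detection(bbox(0, 0, 10, h_for(0.4)), 1)),
                gts = list(g)),
    img2 = list(preds = list(detection(bbox(0, 0, 10, h_for(0.6)), 1)),
                gts = list(g)))
  rep1 <- evaluate_detections(per, threshold = 0.7)
  expect_equal(rep1$mean_iou, 0.5, tolerance = 1e-12)
  expect_equal(rep1$sd_iou, 0.1, tolerance = 1e-12)  # population SD

  rep2 <- evaluate_detections(rev(per), threshold = 0.7)
  expect_equal(rep2$mean_iou, rep1$mean_iou)
  expect_equal(rep2$sd_iou, rep1$sd_iou)
  expect_equal(rep2$mean_euclid, rep1$mean_euclid)

  # report is consistent with its own per-image export
  expect_equal(mean(rep1$per_image$iou), rep1$mean_iou, tolerance = 1e-9)
  expect_equal(sqrt(mean((rep1$per_image$iou - rep1$mean_iou)^2)),
               rep1$sd_iou, tolerance = 1e-9)

  expect_error(evaluate_detections(list()), "at least one")
})

test_that("lowering the threshold never loses matched ground truth", {
  set.seed(55)
  for (i in 1:10) {
    gts <- replicate(4, random_bbox(60, 60, 6), simplify = FALSE)
    preds <- lapply(gts, function(b) {
      detection(bbox(b[["x_min"]], b[["y_min"]],
                     b[["x_max"]] + runif(1, 0, 3),
                     b[["y_max"]] + runif(1, 0, 3)), runif(1))
    })
    matched_at <- function(th)
      image_score(preds, gts, th)$n_matched
    counts <- vapply(c(0.9, 0.7, 0.4, 0), matched_at, numeric(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("detection CSV adapter round-trips", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(image_id = c("a", "a", "b"),
                   x_min = c(0, 5, 1), y_min = c(0, 5, 1),
                   x_max = c(4, 9, 3), y_max = c(4, 9, 3),
                   confidence = c(0.9, 0.5, 0.7))
  utils::write.csv(df, path, row.names = FALSE)
  dets <- read_detections_csv(path)
  expect_length(dets$a, 2)
  expect_length(dets$b, 1)
  expect_equal(dets$b[[1]]$confidence, 0.7)
})
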