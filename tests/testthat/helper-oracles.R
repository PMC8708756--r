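# Independent oracles used across the suite. These deliberately take a
# different computational route from the package implementation.

# L-system expansion by depth-first recursion with memoised per-symbol
# expansion at each depth (vs the package's iterative whole-string rewrite)
oracle_expand <- function(axiom, rules, iterations) {
  memo <- new.env(parent = emptyenv())
  expand_sym <- function(sym, n) {
    if (n == 0L) return(sym)
    key <- paste0(sym, "@", n)
    if (!is.null(memo[[key]])) return(memo[[key]])
    repl <- rules[[sym]]
    if (is.null(repl)) repl <- sym
    parts <- vapply(strsplit(repl, "")[[1]], expand_sym, character(1),
                    n = n - 1L)
    out <- paste0(parts, collapse = "")
    memo[[key]] <- out
    out
  }
  paste0(vapply(strsplit(axiom, "")[[1]], expand_sym, character(1),
                n = iterations), collapse = "")
}

# stratified (jittered-grid) Monte-Carlo IoU over the union's bounding
# region; n is rounded up to a square grid
mc_iou <- function(a, b, n = 1e6) {
  lo_x <- min(a[["x_min"]], b[["x_min"]])
  hi_x <- max(a[["x_max"]], b[["x_max"]])
  lo_y <- min(a[["y_min"]], b[["y_min"]])
  hi_y <- max(a[["y_max"]], b[["y_max"]])
  g <- ceiling(sqrt(n))
  xs <- lo_x + (rep(seq_len(g), times = g) - stats::runif(g * g)) *
    (hi_x - lo_x) / g
  ys <- lo_y + (rep(seq_len(g), each = g) - stats::runif(g * g)) *
    (hi_y - lo_y) / g
  in_a <- xs >= a[["x_min"]] & xs <= a[["x_max"]] &
    ys >= a[["y_min"]] & ys <= a[["y_max"]]
  in_b <- xs >= b[["x_min"]] & xs <= b[["x_max"]] &
    ys >= b[["y_min"]] & ys <= b[["y_max"]]
  n_u <- sum(in_a | in_b)
  if (n_u == 0) return(0)
  sum(in_a & in_b) / n_u
}

# best one-to-one assignment by total IoU over all injections (preds <= 4,
# gts <= 4); returns the pair set of the optimum
brute_force_match <- function(preds, gts) {
  np <- length(preds)
  ng <- length(gts)
  iou_m <- outer(seq_len(np), seq_len(ng),
                 Vectorize(function(i, j) iou(preds[[i]], gts[[j]])))
  best <- list(score = -1, pairs = NULL)
  k <- min(np, ng)
  if (k == 0) return(best)
  for (m in k:1) {
    pred_sets <- utils::combn(np, m, simplify = FALSE)
    gt_perms <- perms(ng, m)
    for (ps in pred_sets) for (gp in gt_perms) {
      ious <- iou_m[cbind(ps, gp)]
      if (any(ious <= 0)) next
      sc <- sum(ious)
      if (sc > best$score) best <- list(score = sc, pairs = cbind(ps, gp))
    }
  }
  best
}

bf_iou_matrix <- function(preds, gts) {
  outer(seq_along(preds), seq_along(gts),
        Vectorize(function(i, j) iou(preds[[i]], gts[[j]])))
}

# all ordered m-tuples from 1..n
perms <- function(n, m) {
  if (m == 0) return(list(integer(0)))
  out <- list()
  rec <- function(cur, remaining) {
    if (length(cur) == m) {
      out[[length(out) + 1L]] <<- cur
      return()
    }
    for (x in remaining) rec(c(cur, x), setdiff(remaining, x))
  }
  rec(integer(0), seq_len(n))
  out
}

random_bbox <- function(max_w = 100, max_h = 100, min_side = 2) {
  x0 <- stats::runif(1, 0, max_w - min_side)
  y0 <- stats::runif(1, 0, max_h - min_side)
  bbox(x0, y0, x0 + stats::runif(1, min_side, max_w - x0),
       y0 + stats::runif(1, min_side, max_h - y0))
}

# a pair of boxes guaranteed to overlap (for matching/IoU tests)
overlapping_bbox_pair <- function(size = 20) {
  a <- random_bbox(80, 80)
  shift <- stats::runif(2, -0.3, 0.3) *
    c(bbox_width(a), bbox_height(a))
  b <- bbox(a[["x_min"]] + shift[1], a[["y_min"]] + shift[2],
            a[["x_max"]] + shift[1], a[["y_max"]] + shift[2])
  list(a = a, b = b)
}

tiny_cam <- function(size = 64L, f = 80)
  overhead_camera(altitude = 3, focal_px = f, width = size, height = size)
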