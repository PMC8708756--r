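# Annotation CSV input/output. Two dialects are supported and auto-detected
# by header:
#   internal: image_id,width,height,x_min,y_min,x_max,y_max  (one row per box)
#   GWHC:     image_id,width,height,bbox with bbox = "[x, y, w, h]"
#             (x, y = top-left corner) as used by the Global Wheat Head
#             Challenge annotation files.

#' Write annotations to CSV
#'
#' @param annotations list of [scene_annotation()] records.
#' @param path output file.
#' @param dialect `"internal"` (corner coordinates, one row per box) or
#'   `"gwhc"` (a `[x, y, w, h]` string per box).
#' @return `path`, invisibly.
#' @export
write_annotations_csv <- function(annotations, path,
                                  dialect = c("internal", "gwhc")) {
  dialect <- match.arg(dialect)
  rows <- lapply(annotations, function(ann) {
    stopifnot(inherits(ann, "scene_annotation"))
    if (!length(ann$boxes)) return(NULL)
    do.call(rbind, lapply(ann$boxes, function(b) {
      data.frame(image_id = ann$image_id, width = ann$width,
                 height = ann$height,
                 x_min = b[["x_min"]], y_min = b[["y_min"]],
                 x_max = b[["x_max"]], y_max = b[["y_max"]],
                 stringsAsFactors = FALSE)
    }))
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(image_id = character(), width = integer(),
                     height = integer(), x_min = numeric(), y_min = numeric(),
                     x_max = numeric(), y_max = numeric())
  if (dialect == "gwhc") {
    df <- data.frame(
      image_id = df$image_id, width = df$width, height = df$height,
      bbox = sprintf("[%s, %s, %s, %s]",
                     format(df$x_min, trim = TRUE, digits = 10),
                     format(df$y_min, trim = TRUE, digits = 10),
                     format(df$x_max - df$x_min, trim = TRUE, digits = 10),
                     format(df$y_max - df$y_min, trim = TRUE, digits = 10)),
      stringsAsFactors = FALSE)
    if (!nrow(df)) df$bbox <- character(0)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read annotations from CSV
#'
#' Auto-detects the dialect from the header line. Images listed with no valid
#' rows are omitted; empty files round-trip to an empty list.
#'
#' @param path CSV file.
#' @return Named list of [scene_annotation()] records keyed by image id.
#' @export
read_annotations_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  internal_cols <- c("image_id", "width", "height",
                     "x_min", "y_min", "x_max", "y_max")
  gwhc_cols <- c("image_id", "width", "height", "bbox")
  if (all(internal_cols %in% names(df))) {
    dialect <- "internal"
  } else if (all(gwhc_cols %in% names(df))) {
    dialect <- "gwhc"
  } else {
    stopf("unrecognised annotation header: %s", paste(names(df), collapse = ","))
  }
  if (dialect == "gwhc" && nrow(df)) {
    coords <- lapply(seq_len(nrow(df)), function(i) {
      s <- gsub("\\[|\\]", "", df$bbox[i])
      v <- suppressWarnings(as.numeric(strsplit(s, ",")[[1]]))
      if (length(v) != 4 || anyNA(v))
        stopf("malformed bbox string at data row %d: '%s'", i, df$bbox[i])
      v
    })
    m <- do.call(rbind, coords)
    df$x_min <- m[, 1]
    df$y_min <- m[, 2]
    df$x_max <- m[, 1] + m[, 3]
    df$y_max <- m[, 2] + m[, 4]
  }
  out <- list()
  if (!nrow(df)) return(out)
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    if (anyNA(row[c("x_min", "y_min", "x_max", "y_max")]) ||
        row$x_min >= row$x_max || row$y_min >= row$y_max)
      stopf("malformed annotation at data row %d of %s", i, path)
    id <- as.character(row$image_id)
    b <- bbox(row$x_min, row$y_min, row$x_max, row$y_max)
    if (is.null(out[[id]])) {
      out[[id]] <- scene_annotation(id, row$width, row$height, list(b))
    } else {
      if (out[[id]]$width != row$width || out[[id]]$height != row$height)
        stopf("inconsistent dimensions for image '%s' at row %d", id, i)
      out[[id]]$boxes <- c(out[[id]]$boxes, list(b))
    }
  }
  out
}
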