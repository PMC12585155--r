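.class_index <- c(defect = 0L, vesicle = 1L)
.index_class <- c("defect", "vesicle")

#' Read / write YOLO label files
#'
#' YOLO text labels hold one object per line:
#' `class_index x_center y_center width height`, all coordinates normalized
#' to `[0, 1]` by the image size. Class indices are fixed package-wide:
#' defect = 0, vesicle = 1. An empty (or absent) label file denotes a
#' background image. Round-tripping preserves box coordinates to well under
#' half a pixel.
#'
#' @param path Label file path.
#' @param image_size `c(width, height)` of the labelled image in pixels.
#' @param ann Annotation data frame (boxes in image pixel coordinates).
#' @param z,stack_id,rater Metadata stamped onto rows read back.
#' @return `yolo_read()` returns an annotation data frame; `yolo_write()`
#'   returns `path` invisibly.
#' @export
yolo_read <- function(path, image_size, z = 0L, stack_id = "stack",
                      rater = "yolo") {
  out <- annotation_df()
  if (!file.exists(path)) return(out)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(out)
  fields <- lapply(strsplit(trimws(lines), "[[:space:]]+"), as.numeric)
  if (any(vapply(fields, length, 1L) != 5))
    stop("malformed YOLO label line in ", path)
  m <- do.call(rbind, fields)
  if (any(m[, 2:5] < 0) || any(m[, 2:5] > 1))
    stop("YOLO coordinates outside [0, 1] in ", path)
  if (any(!m[, 1] %in% c(0, 1))) stop("unknown class index in ", path)
  data.frame(stack_id = stack_id, class = .index_class[m[, 1] + 1],
             x_min = (m[, 2] - m[, 4] / 2) * image_size[1],
             y_min = (m[, 3] - m[, 5] / 2) * image_size[2],
             x_max = (m[, 2] + m[, 4] / 2) * image_size[1],
             y_max = (m[, 3] + m[, 5] / 2) * image_size[2],
             z = as.integer(z), rater = rater, stringsAsFactors = FALSE)
}

#' @rdname yolo_read
#' @export
yolo_write <- function(ann, path, image_size) {
  if (nrow(ann) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  check_boxes(ann)
  cx <- (ann$x_min + ann$x_max) / 2 / image_size[1]
  cy <- (ann$y_min + ann$y_max) / 2 / image_size[2]
  bw <- (ann$x_max - ann$x_min) / image_size[1]
  bh <- (ann$y_max - ann$y_min) / image_size[2]
  if (any(c(cx, cy, bw, bh) < -1e-9) || any(c(cx, cy, bw, bh) > 1 + 1e-9))
    stop("box outside image; clip before exporting YOLO labels")
  idx <- .class_index[ann$class]
  if (any(is.na(idx))) stop("unknown class label")
  writeLines(sprintf("%d %.9f %.9f %.9f %.9f", idx, cx, cy, bw, bh), path)
  invisible(path)
}

#' Read / write a detection set as JSON
#'
#' Interchange format for volumetric detections:
#' `{"stack_id": ..., "detections": [{"class", "x_min", "y_min", "x_max",
#' "y_max", "z", "confidence"}, ...]}`.
#'
#' @param det Detection data frame (single `stack_id`).
#' @param path JSON file path.
#' @return `read_detections()` returns a detection data frame;
#'   `write_detections()` returns `path` invisibly.
#' @export
write_detections <- function(det, path) {
  check_boxes(det)
  sid <- if (nrow(det)) unique(det$stack_id) else "stack"
  if (length(sid) != 1) stop("write_detections expects a single stack_id")
  jsonlite::write_json(
    list(stack_id = sid,
         detections = det[, c("class", "x_min", "y_min", "x_max", "y_max",
                              "z", "confidence")]),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$detections) || length(obj$detections) == 0 ||
      NROW(obj$detections) == 0)
    return(detection_df())
  det <- as.data.frame(obj$detections)
  det$stack_id <- obj$stack_id
  det$z <- as.integer(det$z)
  check_boxes(det[, c("stack_id", "class", "x_min", "y_min", "x_max",
                      "y_max", "z", "confidence")])
}

#' Read / write a review ledger CSV
#'
#' A review ledger records one expert decision per proposal:
#' `proposal_id, decision, reviewer`, with `decision` one of `accept`,
#' `reject_background` (a challenging false positive to be re-used as a
#' background training image) or `reject_discard`.
#'
#' @param ledger Data frame with columns `proposal_id`, `decision`,
#'   `reviewer`.
#' @param path CSV file path.
#' @return `read_ledger()` returns the ledger data frame; `write_ledger()`
#'   returns `path` invisibly.
#' @export
read_ledger <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("proposal_id", "decision", "reviewer")
  if (!all(need %in% names(df)))
    stop("ledger must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(df$decision),
                 c("accept", "reject_background", "reject_discard"))
  if (length(bad)) stop("unknown decisions: ", paste(bad, collapse = ", "))
  df
}

#' @rdname read_ledger
#' @export
write_ledger <- function(ledger, path) {
  utils::write.csv(ledger, path, row.names = FALSE)
  invisible(path)
}
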