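#' Empty detection data frame
#'
#' Detections are plain data frames with one row per detected object in
#' global stack coordinates: `stack_id`, `class` (`"defect"` or `"vesicle"`),
#' 0-based half-open box `x_min`/`y_min`/`x_max`/`y_max` (px), 0-based plane
#' `z`, and `confidence` in `[0, 1]`.
#'
#' @return A zero-row data frame with the detection columns.
#' @export
detection_df <- function() {
  data.frame(stack_id = character(0), class = character(0),
             x_min = numeric(0), y_min = numeric(0),
             x_max = numeric(0), y_max = numeric(0),
             z = integer(0), confidence = numeric(0),
             stringsAsFactors = FALSE)
}

#' Empty annotation data frame
#'
#' Annotations share the detection geometry but carry a `rater` identifier
#' (an expert id, `"model+review"`, or `"phantom"`) instead of a confidence.
#'
#' @return A zero-row data frame with the annotation columns.
#' @export
annotation_df <- function() {
  data.frame(stack_id = character(0), class = character(0),
             x_min = numeric(0), y_min = numeric(0),
             x_max = numeric(0), y_max = numeric(0),
             z = integer(0), rater = character(0),
             stringsAsFactors = FALSE)
}

# Validate box geometry on a detection/annotation frame.
check_boxes <- function(df) {
  if (nrow(df) == 0) return(invisible(df))
  if (any(df$x_max <= df$x_min) || any(df$y_max <= df$y_min))
    stop("degenerate box: max must exceed min")
  if (!is.null(df$confidence) &&
      (any(df$confidence < 0) || any(df$confidence > 1)))
    stop("confidence must lie in [0, 1]")
  invisible(df)
}

# rbind that tolerates zero-row pieces and returns a canonical empty frame.
bind_rows_ <- function(lst, empty) {
  lst <- Filter(function(x) !is.null(x) && nrow(x) > 0, lst)
  if (length(lst) == 0) return(empty)
  out <- do.call(rbind, lst)
  rownames(out) <- NULL
  out
}
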