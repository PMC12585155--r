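#' Sliding-window plan with overlap and edge clamping
#'
#' Window origins along each axis form a stride grid
#' `0, stride, 2 * stride, ...` with `stride = size * (1 - overlap_fraction)`
#' (50% overlap by default, which desensitizes tiled detectors to small
#' translations). If the last stride-grid window does not reach the image
#' edge, a clamped window at `dim - size` is appended so every pixel is
#' covered without inventing padding.
#'
#' @param width,height Image size in pixels.
#' @param size Window side in pixels (default 100).
#' @param overlap_fraction Overlap between adjacent windows in `[0, 1)`.
#' @return List with sorted unique integer vectors `x0` and `y0` of 0-based
#'   window origins, plus `size` and `stride`.
#' @examples
#' length(plan_windows(2960, 2960)$x0)  # 59 origins per axis
#' @export
plan_windows <- function(width, height, size = 100, overlap_fraction = 0.5) {
  stopifnot(size >= 1, overlap_fraction >= 0, overlap_fraction < 1)
  if (size > width || size > height)
    stop("window size exceeds image dimension")
  stride <- max(1L, as.integer(round(size * (1 - overlap_fraction))))
  axis <- function(dim) {
    o <- seq.int(0L, dim - size, by = stride)
    if (o[length(o)] + size < dim) o <- c(o, dim - size)
    as.integer(o)
  }
  list(x0 = axis(as.integer(width)), y0 = axis(as.integer(height)),
       size = as.integer(size), stride = stride)
}

#' Window specification
#'
#' A `size x size` crop at origin `(x0, y0)` of plane `z`, upsampled to
#' `upsample_to` pixels for the detector; the coordinate scale factor is
#' `upsample_to / size` (6.4 for the 100 -> 640 default).
#'
#' @param x0,y0 0-based window origin (px).
#' @param z 0-based plane index.
#' @param size Window side (px).
#' @param upsample_to Side of the upsampled image (px).
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(x0, y0, z = 0L, size = 100L, upsample_to = 640L) {
  stopifnot(x0 >= 0, y0 >= 0, z >= 0, size >= 1, upsample_to >= size)
  structure(list(x0 = as.integer(x0), y0 = as.integer(y0), z = as.integer(z),
                 size = as.integer(size), upsample_to = as.integer(upsample_to),
                 scale = upsample_to / size),
            class = "window_spec")
}

#' Extract and upsample a window from a stack
#'
#' Crops `size x size` pixels from plane `z` and resizes to
#' `upsample_to x upsample_to` with bilinear interpolation (enlarging the
#' apparent object size mitigates small-object detection limits).
#'
#' @param stack A [zstack()].
#' @param w A [window_spec()].
#' @return `(upsample_to, upsample_to, n_channels)` array.
#' @export
extract_window <- function(stack, w) {
  stopifnot(inherits(stack, "zstack"), inherits(w, "window_spec"))
  d <- dim(stack$voxels)
  if (w$z >= d[1] || w$x0 + w$size > d[3] || w$y0 + w$size > d[2])
    stop("window outside stack bounds")
  crop <- stack$voxels[w$z + 1L, w$y0 + seq_len(w$size),
                       w$x0 + seq_len(w$size), , drop = FALSE]
  crop <- array(crop, dim(crop)[-1])
  if (w$upsample_to == w$size) return(crop)
  out <- array(0, c(w$upsample_to, w$upsample_to, d[4]))
  for (ci in seq_len(d[4]))
    out[, , ci] <- EBImage::resize(crop[, , ci], w = w$upsample_to,
                                   h = w$upsample_to, filter = "bilinear")
  out
}

#' Map window-local detections back to global stack coordinates
#'
#' Inverts the crop-and-upsample transform: box coordinates are divided by
#' the window scale factor, offset by the window origin, clamped to the
#' stack bounds, and stamped with the window's plane index.
#'
#' @param det Detection data frame in upsampled-window coordinates.
#' @param w The generating [window_spec()].
#' @param stack_dim Optional `dim(stack$voxels)` for clamping.
#' @param stack_id Stack identifier to stamp.
#' @return Detection data frame in global coordinates.
#' @export
map_to_global <- function(det, w, stack_dim = NULL, stack_id = "stack") {
  if (nrow(det) == 0) return(detection_df())
  out <- det
  out$x_min <- det$x_min / w$scale + w$x0
  out$x_max <- det$x_max / w$scale + w$x0
  out$y_min <- det$y_min / w$scale + w$y0
  out$y_max <- det$y_max / w$scale + w$y0
  out$z <- w$z
  out$stack_id <- stack_id
  if (!is.null(stack_dim)) {
    out$x_min <- pmax(0, pmin(out$x_min, stack_dim[3]))
    out$x_max <- pmax(0, pmin(out$x_max, stack_dim[3]))
    out$y_min <- pmax(0, pmin(out$y_min, stack_dim[2]))
    out$y_max <- pmax(0, pmin(out$y_max, stack_dim[2]))
  }
  out[, c("stack_id", "class", "x_min", "y_min", "x_max", "y_max", "z",
          "confidence")]
}

# Global box -> coordinates of the upsampled window image (inverse of
# map_to_global); used by the oracle detector and dataset export.
map_to_window <- function(df, w) {
  out <- df
  out$x_min <- (df$x_min - w$x0) * w$scale
  out$x_max <- (df$x_max - w$x0) * w$scale
  out$y_min <- (df$y_min - w$y0) * w$scale
  out$y_max <- (df$y_max - w$y0) * w$scale
  out
}
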