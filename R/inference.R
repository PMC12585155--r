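#' Intersection over union of two boxes
#'
#' Boxes are 0-based half-open `[min, max)` rectangles, so areas are
#' `(x_max - x_min) * (y_max - y_min)` with no off-by-one ambiguity.
#'
#' @param a,b Length-4 vectors or one-row data frames with
#'   `x_min, y_min, x_max, y_max`.
#' @return IoU in `[0, 1]`.
#' @examples
#' iou(c(0, 0, 10, 10), c(5, 0, 15, 10))  # 1/3
#' @export
iou <- function(a, b) {
  a <- as_box(a); b <- as_box(b)
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) -
    inter
  if (union <= 0) 0 else inter / union
}

as_box <- function(x) {
  if (is.data.frame(x))
    x <- as.numeric(x[1, c("x_min", "y_min", "x_max", "y_max")])
  stopifnot(length(x) == 4)
  x
}

# Pairwise IoU matrix between the rows of two box frames (vectorized).
iou_matrix <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(matrix(0, nrow(a), nrow(b)))
  ix <- pmax(0, outer(a$x_max, b$x_max, pmin) - outer(a$x_min, b$x_min, pmax))
  iy <- pmax(0, outer(a$y_max, b$y_max, pmin) - outer(a$y_min, b$y_min, pmax))
  inter <- ix * iy
  area_a <- (a$x_max - a$x_min) * (a$y_max - a$y_min)
  area_b <- (b$x_max - b$x_min) * (b$y_max - b$y_min)
  un <- outer(area_a, area_b, `+`) - inter
  out <- inter / un
  out[un <= 0] <- 0
  out
}

#' Greedy non-maximum suppression
#'
#' Keeps the highest-confidence detection, removes all remaining detections
#' overlapping it with IoU >= `iou_threshold`, and repeats. Intended to run
#' per z-plane and per class (cross-plane redundancy is handled by the
#' vesicle chain filter instead).
#'
#' @param det Detection data frame (one plane, one class).
#' @param iou_threshold Suppression threshold in `(0, 1]`.
#' @return The surviving subset, in descending confidence order; no two
#'   survivors overlap with IoU >= `iou_threshold`.
#' @export
nms <- function(det, iou_threshold = 0.5) {
  if (nrow(det) <= 1) return(det)
  ord <- order(-det$confidence)
  det <- det[ord, ]
  m <- iou_matrix(det, det)
  keep <- logical(nrow(det))
  alive <- rep(TRUE, nrow(det))
  for (i in seq_len(nrow(det))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[m[i, ] >= iou_threshold] <- FALSE
  }
  out <- det[keep, ]
  rownames(out) <- NULL
  out
}

#' Link same-class detections across consecutive z-planes
#'
#' Greedily links each detection to the best-IoU unclaimed detection of the
#' same class on the next plane when their IoU is at least `link_iou`.
#' Chains are maximal runs over strictly consecutive planes; every detection
#' belongs to exactly one chain.
#'
#' @param det Detection data frame (one class, NMS already applied per
#'   plane).
#' @param link_iou Minimum IoU to continue a chain.
#' @return `det` with an integer `chain_id` column and a `span` column
#'   giving the number of consecutive planes of the detection's chain.
#' @export
link_chains <- function(det, link_iou = 0.2) {
  if (nrow(det) == 0) {
    det$chain_id <- integer(0); det$span <- integer(0)
    return(det)
  }
  stopifnot(length(unique(det$class)) == 1)
  det <- det[order(det$z, -det$confidence), ]
  rownames(det) <- NULL
  chain <- rep(NA_integer_, nrow(det))
  next_id <- 1L
  zs <- sort(unique(det$z))
  for (z in zs) {
    cur <- which(det$z == z)
    unassigned <- cur[is.na(chain[cur])]
    if (length(unassigned)) {
      chain[unassigned] <- next_id + seq_along(unassigned) - 1L
      next_id <- next_id + length(unassigned)
    }
    nxt <- which(det$z == z + 1L)
    if (length(nxt) == 0) next
    m <- iou_matrix(det[cur, ], det[nxt, ])
    claimed <- logical(length(nxt))
    # each current-plane detection claims its best available successor
    for (i in seq_along(cur)) {
      cand <- which(!claimed & m[i, ] >= link_iou)
      if (length(cand) == 0) next
      j <- cand[which.max(m[i, cand])]
      chain[nxt[j]] <- chain[cur[i]]
      claimed[j] <- TRUE
    }
  }
  det$chain_id <- chain
  span <- tapply(det$z, chain, function(z) length(unique(z)))
  det$span <- as.integer(span[as.character(chain)])
  det
}

#' Z-plane filter for transverse-axon false positives
#'
#' Removes vesicle detections whose chain spans three or more consecutive
#' z-planes: a true lipid vesicle is sharp in one focal plane, whereas a
#' transverse axon (an axon perpendicular to the section, seen end-on as a
#' vesicle-like ring) persists across planes. Defect-class detections are
#' never touched.
#'
#' @param det Detection data frame across planes (NMS applied per plane).
#' @param link_iou IoU used to link chains (see [link_chains()]).
#' @param min_span Chains of this span or longer are removed (default 3).
#' @return Filtered detection data frame (without chain columns).
#' @export
z_plane_filter <- function(det, link_iou = 0.2, min_span = 3L) {
  if (nrow(det) == 0) return(det)
  ves <- det[det$class == "vesicle", ]
  other <- det[det$class != "vesicle", ]
  if (nrow(ves)) {
    ves <- link_chains(ves, link_iou = link_iou)
    ves <- ves[ves$span < min_span, ]
    ves$chain_id <- NULL; ves$span <- NULL
  }
  out <- bind_rows_(list(other, ves), detection_df())
  out[order(out$z, out$class, -out$confidence), , drop = FALSE]
}

#' Volumetric sliding-window inference
#'
#' For every z-plane and window of the overlap plan: extract and upsample
#' the window, run the detector, drop detections below its confidence
#' threshold, and map boxes back to global stack coordinates. Pooled
#' detections then pass per-plane per-class NMS and the z-plane vesicle
#' filter. A detector failure on a window is logged and the window skipped.
#'
#' @param stack A [zstack()].
#' @param detector A detector plugin (see [baseline_blob_detector()] /
#'   [oracle_detector()]): a list with `predict(image, window)` and
#'   `conf_threshold`.
#' @param window_size,overlap_fraction,upsample_to Sliding-window geometry.
#' @param nms_iou Per-plane NMS threshold.
#' @param link_iou,min_span Z-plane filter parameters.
#' @param stack_id Identifier stamped on the output.
#' @param verbose Print a progress line per plane.
#' @return Detection data frame in global coordinates; attributes
#'   `windows_processed` and `windows_failed` report coverage.
#' @export
run_inference <- function(stack, detector, window_size = 100,
                          overlap_fraction = 0.5, upsample_to = 640,
                          nms_iou = 0.5, link_iou = 0.2, min_span = 3L,
                          stack_id = "stack", verbose = FALSE) {
  stopifnot(inherits(stack, "zstack"), is.list(detector),
            is.function(detector$predict))
  d <- dim(stack$voxels)
  plan <- plan_windows(d[3], d[2], size = window_size,
                       overlap_fraction = overlap_fraction)
  pooled <- list()
  n_proc <- 0L; n_fail <- 0L
  for (z in 0:(d[1] - 1)) {
    for (y0 in plan$y0) for (x0 in plan$x0) {
      w <- window_spec(x0, y0, z, size = plan$size, upsample_to = upsample_to)
      res <- tryCatch({
        img <- extract_window(stack, w)
        detector$predict(img, w)
      }, error = function(e) e)
      n_proc <- n_proc + 1L
      if (inherits(res, "error")) {
        n_fail <- n_fail + 1L
        warning("detector failed on window (", x0, ",", y0, ",z=", z, "): ",
                conditionMessage(res), call. = FALSE)
        next
      }
      if (is.null(res) || nrow(res) == 0) next
      thr <- detector$conf_threshold %||% 0
      res <- res[res$confidence >= thr, , drop = FALSE]
      if (nrow(res)) pooled[[length(pooled) + 1]] <-
        map_to_global(res, w, stack_dim = d, stack_id = stack_id)
    }
    if (verbose)
      message(sprintf("plane %d: %d windows, %d detections so far",
                      z, length(plan$x0) * length(plan$y0),
                      sum(vapply(pooled, nrow, 1L))))
  }
  det <- bind_rows_(pooled, detection_df())
  if (nrow(det)) {
    parts <- split(det, list(det$z, det$class), drop = TRUE)
    det <- bind_rows_(lapply(parts, nms, iou_threshold = nms_iou),
                      detection_df())
    det <- z_plane_filter(det, link_iou = link_iou, min_span = min_span)
  }
  rownames(det) <- NULL
  attr(det, "windows_processed") <- n_proc
  attr(det, "windows_failed") <- n_fail
  det
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Defect-density heatmap on the sliding-window grid
#'
#' Counts defect-class detections whose box center falls inside each window
#' of the overlap plan. With 50% overlap a detection center can fall in up
#' to four windows and increments each of them; the counts are a density
#' surface, not a partition.
#'
#' @param det Detection data frame in global coordinates.
#' @param width,height Image size (px).
#' @param size,overlap_fraction Window geometry (see [plan_windows()]).
#' @param class_label Which class to count (default `"defect"`).
#' @return Object of class `heatmap_grid`: a `counts` matrix (rows = y
#'   origins, cols = x origins) plus the grid geometry.
#' @export
density_heatmap <- function(det, width, height, size = 100,
                            overlap_fraction = 0.5,
                            class_label = "defect") {
  plan <- plan_windows(width, height, size = size,
                       overlap_fraction = overlap_fraction)
  counts <- matrix(0L, length(plan$y0), length(plan$x0))
  det <- det[det$class == class_label, , drop = FALSE]
  if (nrow(det)) {
    cx <- (det$x_min + det$x_max) / 2
    cy <- (det$y_min + det$y_max) / 2
    for (j in seq_along(plan$x0)) for (i in seq_along(plan$y0)) {
      x0 <- plan$x0[j]; y0 <- plan$y0[i]
      counts[i, j] <- sum(cx >= x0 & cx < x0 + size &
                          cy >= y0 & cy < y0 + size)
    }
  }
  structure(list(counts = counts, x0 = plan$x0, y0 = plan$y0,
                 size = plan$size, stride = plan$stride),
            class = "heatmap_grid")
}

#' Render a heatmap overlay on a focus-stacked projection
#'
#' @param grid A `heatmap_grid` from [density_heatmap()].
#' @param stack The source [zstack()] (used for the grayscale background).
#' @param alpha Overlay opacity in `[0, 1]`.
#' @param path Optional PNG output path.
#' @return `(h, w, 3)` RGB array in `[0, 1]`, invisibly if `path` is given.
#' @export
render_heatmap <- function(grid, stack, alpha = 0.5, path = NULL) {
  stopifnot(inherits(grid, "heatmap_grid"), inherits(stack, "zstack"))
  d <- dim(stack$voxels)
  proj <- max_projection(stack)
  bg <- if (d[4] == 3) 0.299 * proj[, , 1] + 0.587 * proj[, , 2] +
    0.114 * proj[, , 3] else proj[, , 1]
  bg <- bg / max(bg, 1e-12)
  dens <- matrix(0, d[2], d[3]); wsum <- matrix(0, d[2], d[3])
  for (j in seq_along(grid$x0)) for (i in seq_along(grid$y0)) {
    ys <- grid$y0[i] + seq_len(grid$size); xs <- grid$x0[j] + seq_len(grid$size)
    dens[ys, xs] <- dens[ys, xs] + grid$counts[i, j]
    wsum[ys, xs] <- wsum[ys, xs] + 1
  }
  dens <- dens / pmax(wsum, 1)
  dens <- dens / max(dens, 1e-12)
  # dark blue (low) -> bright yellow (high)
  out <- array(0, c(d[2], d[3], 3))
  out[, , 1] <- (1 - alpha) * bg + alpha * dens
  out[, , 2] <- (1 - alpha) * bg + alpha * dens
  out[, , 3] <- (1 - alpha) * bg + alpha * (0.4 * (1 - dens))
  out <- pmin(pmax(out, 0), 1)
  if (!is.null(path)) {
    png::writePNG(out, path)
    return(invisible(out))
  }
  out
}
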