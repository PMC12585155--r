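#' Export pseudo-label proposals for expert review
#'
#' Keeps detections at or above the pseudo-labeling confidence threshold
#' (deliberately lower than a deployment threshold, so that false negatives
#' — which the review cannot correct, since reviewers never add boxes — are
#' rare) and assigns stable proposal ids. Optionally writes a reviewable CSV
#' and a per-proposal window crop for each proposal.
#'
#' @param det Detection data frame.
#' @param pseudo_conf_threshold Confidence threshold in `[0, 1]`
#'   (default 0.15).
#' @param iteration Human-in-the-loop iteration number (>= 1).
#' @param dir Optional output directory for `proposals.csv` and crops.
#' @param stack Optional [zstack()]; when given together with `dir`, a
#'   100 x 100 crop around each proposal is written as PNG for review.
#' @return Object of class `proposal_batch`: list with `iteration`,
#'   `threshold`, `proposals` (detections plus `proposal_id`), `stack_ids`.
#' @export
export_proposals <- function(det, pseudo_conf_threshold = 0.15,
                             iteration = 1L, dir = NULL, stack = NULL) {
  stopifnot(pseudo_conf_threshold >= 0, pseudo_conf_threshold <= 1,
            iteration >= 1)
  keep <- det[det$confidence >= pseudo_conf_threshold, , drop = FALSE]
  keep <- keep[order(keep$z, keep$x_min, keep$y_min), , drop = FALSE]
  rownames(keep) <- NULL
  if (nrow(keep))
    keep$proposal_id <- sprintf("it%02d-p%05d", iteration, seq_len(nrow(keep)))
  else keep$proposal_id <- character(0)
  batch <- structure(list(iteration = as.integer(iteration),
                          threshold = pseudo_conf_threshold,
                          proposals = keep,
                          stack_ids = unique(keep$stack_id)),
                     class = "proposal_batch")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(keep, file.path(dir, "proposals.csv"), row.names = FALSE)
    if (!is.null(stack) && nrow(keep)) {
      d <- dim(stack$voxels)
      for (i in seq_len(nrow(keep))) {
        w <- enclosing_window(keep[i, ], d)
        img <- extract_window(stack, window_spec(w$x0, w$y0, keep$z[i],
                                                 size = w$size,
                                                 upsample_to = w$size))
        img <- img / max(img, 1e-12)
        if (dim(img)[3] == 1) img <- img[, , 1]
        png::writePNG(pmin(pmax(img, 0), 1),
                      file.path(dir, paste0(keep$proposal_id[i], ".png")))
      }
    }
  }
  batch
}

# The inference window (stride grid of the 50%-overlap plan) whose center is
# nearest the box center; used to position background crops.
enclosing_window <- function(row, stack_dim, size = 100L) {
  stride <- size %/% 2L
  cx <- (row$x_min + row$x_max) / 2
  cy <- (row$y_min + row$y_max) / 2
  snap <- function(c_, dim) {
    o <- round((c_ - size / 2) / stride) * stride
    as.integer(min(max(o, 0), dim - size))
  }
  list(x0 = snap(cx, stack_dim[3]), y0 = snap(cy, stack_dim[2]),
       size = as.integer(size))
}

#' Ingest an expert review ledger
#'
#' Resolves every proposal of a batch against the expert decisions:
#' `accept` turns the proposal into an annotation with
#' `rater = "model+review"`; `reject_background` exports the enclosing
#' 100 x 100 inference window as a background training image (deduplicated
#' by window origin and plane); `reject_discard` drops the proposal. Only
#' accepted proposals can ever reach a training set.
#'
#' @param batch A `proposal_batch` from [export_proposals()].
#' @param ledger Review ledger data frame (`proposal_id`, `decision`,
#'   `reviewer`); must cover every proposal id exactly once.
#' @param stack_dim `dim(stack$voxels)` used to clamp background windows.
#' @param window_size Background window side (px).
#' @return List with `accepted` (annotation data frame) and `backgrounds`
#'   (data frame of `stack_id`, `x0`, `y0`, `z`, `size`).
#' @export
ingest_review <- function(batch, ledger, stack_dim = NULL,
                          window_size = 100L) {
  stopifnot(inherits(batch, "proposal_batch"))
  props <- batch$proposals
  ids <- props$proposal_id
  missing <- setdiff(ids, ledger$proposal_id)
  unknown <- setdiff(ledger$proposal_id, ids)
  dup <- unique(ledger$proposal_id[duplicated(ledger$proposal_id)])
  if (length(missing) || length(unknown) || length(dup))
    stop("ledger error: ",
         if (length(missing)) paste0("unresolved ids [",
                                     paste(missing, collapse = ", "), "] "),
         if (length(unknown)) paste0("unknown ids [",
                                     paste(unknown, collapse = ", "), "] "),
         if (length(dup)) paste0("duplicate ids [",
                                 paste(dup, collapse = ", "), "]"))
  dec <- ledger$decision[match(ids, ledger$proposal_id)]
  acc <- props[dec == "accept", , drop = FALSE]
  accepted <- if (nrow(acc)) data.frame(
    stack_id = acc$stack_id, class = acc$class,
    x_min = acc$x_min, y_min = acc$y_min, x_max = acc$x_max,
    y_max = acc$y_max, z = acc$z, rater = "model+review",
    iteration = batch$iteration, stringsAsFactors = FALSE) else
    transform(annotation_df(), iteration = integer(0))
  bgp <- props[dec == "reject_background", , drop = FALSE]
  if (nrow(bgp)) {
    if (is.null(stack_dim))
      stack_dim <- c(max(bgp$z) + 1L,
                     ceiling(max(bgp$y_max)) + window_size,
                     ceiling(max(bgp$x_max)) + window_size, 1L)
    wins <- lapply(seq_len(nrow(bgp)), function(i) {
      w <- enclosing_window(bgp[i, ], stack_dim, size = window_size)
      data.frame(stack_id = bgp$stack_id[i], x0 = w$x0, y0 = w$y0,
                 z = bgp$z[i], size = w$size, iteration = batch$iteration,
                 stringsAsFactors = FALSE)
    })
    backgrounds <- unique(do.call(rbind, wins))
    rownames(backgrounds) <- NULL
  } else {
    backgrounds <- data.frame(stack_id = character(0), x0 = integer(0),
                              y0 = integer(0), z = integer(0),
                              size = integer(0), iteration = integer(0))
  }
  list(accepted = accepted, backgrounds = backgrounds)
}

#' Assemble the cumulative training dataset
#'
#' Takes the accepted annotations and background windows of one or more
#' human-in-the-loop iterations (see [ingest_review()]) and assembles the
#' cumulative dataset: one 100 x 100 window (upsampled on export) per
#' annotation, centered on it via the inference grid, plus the reviewed
#' background windows with empty label files. Duplicate windows (same stack,
#' origin and plane) are deduplicated, keeping the earliest iteration's
#' provenance. Stacks named in `validation_stacks` must never appear in a
#' training round.
#'
#' @param rounds List of per-iteration lists with elements `accepted` and
#'   `backgrounds` (as returned by [ingest_review()]); de-novo manual
#'   annotations can be supplied in the same shape with their own `rater`.
#' @param validation_stacks Character vector of reserved stack ids.
#' @param out_dir Optional directory; when given together with `stacks`,
#'   window images (PNG) and YOLO labels are written under
#'   `images/` and `labels/`, plus a `manifest.csv`.
#' @param stacks Optional named list mapping stack id to [zstack()].
#' @param window_size,upsample_to Export window geometry.
#' @return Object of class `training_dataset`: list with `records` (one row
#'   per window: stack, origin, z, partition, provenance), `labels` (one row
#'   per exported label line), and `manifest` (per-class and background
#'   counts).
#' @export
assemble_dataset <- function(rounds, validation_stacks = character(0),
                             out_dir = NULL, stacks = NULL,
                             window_size = 100L, upsample_to = 640L) {
  anns <- bind_rows_(lapply(rounds, `[[`, "accepted"),
                     transform(annotation_df(), iteration = integer(0)))
  bgs <- do.call(rbind, c(lapply(rounds, `[[`, "backgrounds"),
                          make.row.names = FALSE))
  if (is.null(bgs))
    bgs <- data.frame(stack_id = character(0), x0 = integer(0),
                      y0 = integer(0), z = integer(0), size = integer(0),
                      iteration = integer(0))
  leaked <- intersect(unique(c(anns$stack_id, bgs$stack_id)),
                      validation_stacks)
  if (length(leaked))
    stop("validation leakage: reserved stack(s) in training rounds: ",
         paste(leaked, collapse = ", "))

  dim_of <- function(sid) {
    if (!is.null(stacks) && sid %in% names(stacks)) dim(stacks[[sid]]$voxels)
    else c(max(anns$z, bgs$z, 0) + 1L, 10^6L, 10^6L, 1L)
  }
  recs <- list(); labs <- list()
  if (nrow(anns)) for (i in seq_len(nrow(anns))) {
    a <- anns[i, ]
    w <- enclosing_window(a, dim_of(a$stack_id), size = window_size)
    recs[[length(recs) + 1]] <- data.frame(
      stack_id = a$stack_id, x0 = w$x0, y0 = w$y0, z = a$z,
      kind = "annotated", iteration = a$iteration, rater = a$rater,
      partition = "train", stringsAsFactors = FALSE)
  }
  if (nrow(bgs)) for (i in seq_len(nrow(bgs))) {
    b <- bgs[i, ]
    recs[[length(recs) + 1]] <- data.frame(
      stack_id = b$stack_id, x0 = b$x0, y0 = b$y0, z = b$z,
      kind = "background", iteration = b$iteration, rater = "review",
      partition = "train", stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs)
  if (is.null(records))
    records <- data.frame(stack_id = character(0), x0 = integer(0),
                          y0 = integer(0), z = integer(0), kind = character(0),
                          iteration = integer(0), rater = character(0),
                          partition = character(0))
  key <- with(records, paste(stack_id, x0, y0, z, kind))
  records <- records[order(key, records$iteration), ]
  records <- records[!duplicated(with(records, paste(stack_id, x0, y0, z,
                                                     kind))), ]
  # an annotated window supersedes an identical background window
  ann_keys <- with(records[records$kind == "annotated", ],
                   paste(stack_id, x0, y0, z))
  records <- records[!(records$kind == "background" &
                       with(records, paste(stack_id, x0, y0, z)) %in%
                         ann_keys), ]
  records <- records[order(records$stack_id, records$z, records$y0,
                           records$x0, records$kind), ]
  rownames(records) <- NULL
  records$window_id <- sprintf("w%05d", seq_len(nrow(records)))

  # label lines: every annotation intersecting an annotated window, clipped
  if (nrow(anns)) for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (r$kind != "annotated") next
    hit <- anns$stack_id == r$stack_id & anns$z == r$z &
      anns$x_max > r$x0 & anns$x_min < r$x0 + window_size &
      anns$y_max > r$y0 & anns$y_min < r$y0 + window_size
    sub <- anns[hit, , drop = FALSE]
    if (!nrow(sub)) next
    clipped_flag <- sub$x_min < r$x0 | sub$y_min < r$y0 |
      sub$x_max > r$x0 + window_size | sub$y_max > r$y0 + window_size
    sub$x_min <- pmax(sub$x_min, r$x0) - r$x0
    sub$y_min <- pmax(sub$y_min, r$y0) - r$y0
    sub$x_max <- pmin(sub$x_max, r$x0 + window_size) - r$x0
    sub$y_max <- pmin(sub$y_max, r$y0 + window_size) - r$y0
    labs[[length(labs) + 1]] <- data.frame(
      window_id = r$window_id, class = sub$class,
      x_min = sub$x_min, y_min = sub$y_min, x_max = sub$x_max,
      y_max = sub$y_max, clipped = clipped_flag, stringsAsFactors = FALSE)
  }
  labels <- do.call(rbind, labs)
  if (is.null(labels))
    labels <- data.frame(window_id = character(0), class = character(0),
                         x_min = numeric(0), y_min = numeric(0),
                         x_max = numeric(0), y_max = numeric(0),
                         clipped = logical(0))
  rownames(labels) <- NULL

  manifest <- data.frame(
    n_windows = nrow(records),
    n_annotated_windows = sum(records$kind == "annotated"),
    n_background_windows = sum(records$kind == "background"),
    n_defect_labels = sum(labels$class == "defect"),
    n_vesicle_labels = sum(labels$class == "vesicle"),
    n_clipped_labels = sum(labels$clipped))

  ds <- structure(list(records = records, labels = labels,
                       manifest = manifest, window_size = window_size,
                       upsample_to = upsample_to),
                  class = "training_dataset")
  if (!is.null(out_dir)) write_dataset(ds, out_dir, stacks)
  ds
}

# Materialize a training_dataset on disk: images/ (PNG, upsampled windows
# when stacks are available), labels/ (YOLO text), manifest.csv, records.csv.
write_dataset <- function(ds, out_dir, stacks = NULL) {
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "labels"), recursive = TRUE,
             showWarnings = FALSE)
  sc <- ds$upsample_to / ds$window_size
  for (i in seq_len(nrow(ds$records))) {
    r <- ds$records[i, ]
    lab <- ds$labels[ds$labels$window_id == r$window_id, , drop = FALSE]
    ypath <- file.path(out_dir, "labels", paste0(r$window_id, ".txt"))
    if (nrow(lab)) {
      up <- lab
      up[, c("x_min", "y_min", "x_max", "y_max")] <-
        up[, c("x_min", "y_min", "x_max", "y_max")] * sc
      yolo_write(up, ypath, image_size = c(ds$upsample_to, ds$upsample_to))
    } else writeLines(character(0), ypath)
    if (!is.null(stacks) && r$stack_id %in% names(stacks)) {
      img <- extract_window(stacks[[r$stack_id]],
                            window_spec(r$x0, r$y0, r$z,
                                        size = ds$window_size,
                                        upsample_to = ds$upsample_to))
      img <- pmin(pmax(img / max(img, 1e-12), 0), 1)
      if (dim(img)[3] == 1) img <- img[, , 1]
      png::writePNG(img, file.path(out_dir, "images",
                                   paste0(r$window_id, ".png")))
    }
  }
  utils::write.csv(ds$records, file.path(out_dir, "records.csv"),
                   row.names = FALSE)
  utils::write.csv(ds$manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}
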