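#' Consensus ground truth from multiple raters
#'
#' Clusters same-class annotations by single linkage, where boxes from
#' distinct raters are linked when their IoU is at least `iou_min` and their
#' planes differ by at most `z_tol`. Clusters supported by at least
#' `min_raters` distinct raters (2-of-3 by default) become consensus boxes
#' with coordinate-wise mean geometry and integer median z. If a rater
#' contributes several boxes to one cluster, the box with the best mean IoU
#' to the other raters' boxes is used and the duplicate is logged as an
#' attribute.
#'
#' @param ann Annotation data frame from `k` raters (distinct `rater` ids).
#' @param min_raters Minimum distinct supporting raters.
#' @param iou_min Minimum IoU to link two annotations.
#' @param z_tol Maximum plane difference to link two annotations.
#' @return Annotation data frame of consensus boxes with `rater = "consensus"`
#'   and a `support` column; attribute `duplicates` counts rater-duplicate
#'   resolutions.
#' @export
build_consensus <- function(ann, min_raters = 2, iou_min = 0.2, z_tol = 1) {
  if (nrow(ann) == 0) return(transform(annotation_df(), support = integer(0)))
  out <- list(); ndup <- 0L
  for (cls in unique(ann$class)) {
    sub <- ann[ann$class == cls, , drop = FALSE]
    rownames(sub) <- NULL
    n <- nrow(sub)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    m <- iou_matrix(sub, sub)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (j <= i) next
      if (sub$rater[i] != sub$rater[j] && m[i, j] >= iou_min &&
          abs(sub$z[i] - sub$z[j]) <= z_tol) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
    roots <- vapply(seq_len(n), find, 1L)
    for (r in unique(roots)) {
      idx <- which(roots == r)
      grp <- sub[idx, , drop = FALSE]
      support <- length(unique(grp$rater))
      if (support < min_raters) next
      # one box per rater: keep the box best agreeing with the other raters
      pick <- vapply(split(seq_len(nrow(grp)), grp$rater), function(is) {
        if (length(is) == 1) return(is)
        ndup <<- ndup + 1L
        others <- setdiff(seq_len(nrow(grp)), is)
        if (length(others) == 0) return(is[1])
        mi <- iou_matrix(grp[is, , drop = FALSE],
                         grp[others, , drop = FALSE])
        is[which.max(rowMeans(mi))]
      }, 1L)
      grp <- grp[pick, , drop = FALSE]
      out[[length(out) + 1]] <- data.frame(
        stack_id = grp$stack_id[1], class = cls,
        x_min = mean(grp$x_min), y_min = mean(grp$y_min),
        x_max = mean(grp$x_max), y_max = mean(grp$y_max),
        z = as.integer(round(stats::median(grp$z))),
        rater = "consensus", support = support, stringsAsFactors = FALSE)
    }
  }
  res <- bind_rows_(out, transform(annotation_df(), support = integer(0)))
  attr(res, "duplicates") <- ndup
  res
}

#' Greedy one-to-one matching of predictions to ground truth
#'
#' Predictions are visited in descending confidence; each takes the
#' highest-IoU unmatched ground-truth box of the same class satisfying
#' `IoU >= iou_min` and `|z_pred - z_gt| <= z_tol`. Equal-IoU ties break to
#' the smaller plane distance, then the lower ground-truth row index.
#' Leftover predictions are false positives, leftover ground truth false
#' negatives.
#'
#' @param pred Detection data frame.
#' @param gt Ground-truth annotation data frame.
#' @param iou_min Minimum IoU for a match (0.2 in the expert-consensus
#'   validation protocol; 0.5 for AP@50).
#' @param z_tol Plane tolerance (default 1).
#' @return List of class `match_result`: `pairs` (data frame of `pred_idx`,
#'   `gt_idx`, `iou`), `fp_idx`, `fn_idx`, `tp`, `fp`, `fn`, and the
#'   matching parameters.
#' @export
match_detections <- function(pred, gt, iou_min = 0.2, z_tol = 1) {
  np <- nrow(pred); ng <- nrow(gt)
  pairs <- data.frame(pred_idx = integer(0), gt_idx = integer(0),
                      iou = numeric(0))
  if (np > 0 && ng > 0) {
    ord <- order(-pred$confidence)
    m <- iou_matrix(pred, gt)
    zdist <- abs(outer(pred$z, gt$z, `-`))
    ok <- m >= iou_min & zdist <= z_tol &
      outer(pred$class, gt$class, `==`)
    taken <- logical(ng)
    for (i in ord) {
      cand <- which(ok[i, ] & !taken)
      if (length(cand) == 0) next
      best <- cand[order(-m[i, cand], zdist[i, cand], cand)][1]
      taken[best] <- TRUE
      pairs <- rbind(pairs, data.frame(pred_idx = i, gt_idx = best,
                                       iou = m[i, best]))
    }
  }
  structure(list(pairs = pairs,
                 fp_idx = setdiff(seq_len(np), pairs$pred_idx),
                 fn_idx = setdiff(seq_len(ng), pairs$gt_idx),
                 tp = nrow(pairs), fp = np - nrow(pairs),
                 fn = ng - nrow(pairs),
                 iou_min = iou_min, z_tol = z_tol),
            class = "match_result")
}

#' Precision, recall and F1 from match counts
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`,
#' `F1 = 2 * precision * recall / (precision + recall)`; each is defined as
#' 0 when its denominator vanishes.
#'
#' @param tp,fp,fn Non-negative counts, not all zero.
#' @return Named list with `precision`, `recall`, `f1`.
#' @examples
#' precision_recall_f1(1356, 173, 0)$precision  # 0.8868...
#' @export
precision_recall_f1 <- function(tp, fp, fn) {
  if (tp < 0 || fp < 0 || fn < 0) stop("counts must be >= 0")
  if (tp + fp + fn == 0) stop("counts must not all be zero")
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1)
}

#' Average precision (all-point interpolation)
#'
#' Ranks the predictions of one class by descending confidence, assigns
#' true/false-positive status by greedy matching at `iou_min` (0.5 for
#' AP@50) and `z_tol`, and integrates the precision envelope over recall
#' (every-point interpolation). A 101-point COCO-style variant is available
#' for comparison.
#'
#' @param pred Detection data frame of one class.
#' @param gt Ground-truth annotation data frame of the same class; must be
#'   non-empty.
#' @param iou_min IoU threshold for TP status (default 0.5).
#' @param z_tol Plane tolerance.
#' @param interpolation `"all_point"` or `"coco101"`.
#' @return List with `ap`, and the PR curve (`recall`, `precision` vectors in
#'   rank order).
#' @export
average_precision <- function(pred, gt, iou_min = 0.5, z_tol = 1,
                              interpolation = c("all_point", "coco101")) {
  interpolation <- match.arg(interpolation)
  n_gt <- nrow(gt)
  if (n_gt == 0) stop("average precision is undefined with no ground truth")
  if (nrow(pred) == 0)
    return(list(ap = 0, recall = numeric(0), precision = numeric(0)))
  ord <- order(-pred$confidence)
  pred <- pred[ord, , drop = FALSE]
  mr <- match_detections(pred, gt, iou_min = iou_min, z_tol = z_tol)
  tp_flag <- logical(nrow(pred))
  tp_flag[mr$pairs$pred_idx] <- TRUE
  tp_cum <- cumsum(tp_flag)
  fp_cum <- cumsum(!tp_flag)
  recall <- tp_cum / n_gt
  precision <- tp_cum / (tp_cum + fp_cum)
  if (interpolation == "all_point") {
    # precision envelope: running max from the right
    env <- rev(cummax(rev(precision)))
    r_prev <- c(0, recall[-length(recall)])
    ap <- sum((recall - r_prev) * env)
  } else {
    grid <- seq(0, 1, by = 0.01)
    env <- vapply(grid, function(r) {
      i <- which(recall >= r)
      if (length(i) == 0) 0 else max(precision[i])
    }, 1.0)
    ap <- mean(env)
  }
  list(ap = ap, recall = recall, precision = precision)
}

#' Class-frequency-weighted mean average precision
#'
#' `mAP = sum_c (n_c / sum_c n_c) * AP_c`, weighting each class by its
#' ground-truth frequency to account for the defect/vesicle class imbalance.
#'
#' @param ap_per_class Named numeric vector of per-class AP values.
#' @param gt_count_per_class Named numeric vector of ground-truth counts
#'   (> 0) for the same classes.
#' @return Weighted mAP in `[0, 1]`.
#' @examples
#' weighted_map(c(defect = 0.75, vesicle = 0.94),
#'              c(defect = 234, vesicle = 21))
#' @export
weighted_map <- function(ap_per_class, gt_count_per_class) {
  cls <- names(ap_per_class)
  stopifnot(!is.null(cls), all(cls %in% names(gt_count_per_class)))
  n <- gt_count_per_class[cls]
  stopifnot(all(n > 0))
  sum(ap_per_class * n / sum(n))
}

#' Full evaluation report
#'
#' Per-class PR curves and AP at `ap_iou`, class-frequency-weighted mAP,
#' and precision/recall/F1 with TP/FP/FN counts from one-to-one matching at
#' `match_iou` / `z_tol` (the expert-consensus protocol uses
#' `match_iou = 0.2`; AP\@50 always uses `ap_iou = 0.5`).
#'
#' @param pred Detection data frame.
#' @param gt Ground-truth annotation data frame.
#' @param match_iou IoU for the P/R/F1 matching.
#' @param ap_iou IoU for AP (default 0.5).
#' @param z_tol Plane tolerance.
#' @return Object of class `eval_report`.
#' @export
evaluate_detections <- function(pred, gt, match_iou = 0.2, ap_iou = 0.5,
                                z_tol = 1) {
  classes <- sort(unique(gt$class))
  per_class <- list(); aps <- c(); counts <- c()
  for (cls in classes) {
    p <- pred[pred$class == cls, , drop = FALSE]
    g <- gt[gt$class == cls, , drop = FALSE]
    apr <- average_precision(p, g, iou_min = ap_iou, z_tol = z_tol)
    per_class[[cls]] <- apr
    aps[cls] <- apr$ap
    counts[cls] <- nrow(g)
  }
  mr <- match_detections(pred, gt, iou_min = match_iou, z_tol = z_tol)
  prf <- precision_recall_f1(mr$tp, mr$fp, mr$fn)
  structure(list(per_class = per_class, ap_per_class = aps,
                 gt_count_per_class = counts,
                 weighted_map = weighted_map(aps, counts),
                 precision = prf$precision, recall = prf$recall,
                 f1 = prf$f1, tp = mr$tp, fp = mr$fp, fn = mr$fn,
                 match_iou = match_iou, ap_iou = ap_iou, z_tol = z_tol),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> weighted mAP@%d = %.3f | P = %.3f R = %.3f F1 = %.3f (TP %d / FP %d / FN %d)\n",
              round(100 * x$ap_iou), x$weighted_map, x$precision, x$recall,
              x$f1, x$tp, x$fp, x$fn))
  for (cls in names(x$ap_per_class))
    cat(sprintf("  AP[%s] = %.3f (n_gt = %d)\n", cls, x$ap_per_class[cls],
                x$gt_count_per_class[cls]))
  invisible(x)
}

#' Intraclass correlation, two-way model, single measures
#'
#' From the two-way ANOVA mean squares of an `n x k` subjects-by-raters
#' matrix: the consistency form
#' `ICC(C,1) = (MS_rows - MS_err) / (MS_rows + (k - 1) * MS_err)` (the
#' single-measures two-way mixed-effects ICC) with its exact F-based 95% CI,
#' and the absolute-agreement form `ICC(A,1)` with its
#' Satterthwaite-approximation CI. Output labels both forms explicitly.
#'
#' @param ratings Numeric `n x k` matrix, `n >= 2` subjects, `k >= 2`
#'   raters, no missing cells.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `consistency` and `agreement`, each a list of `icc`,
#'   `ci_low`, `ci_high`, plus the mean squares.
#' @export
icc_two_way_mixed_single <- function(ratings, conf_level = 0.95) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  stopifnot(n >= 2, k >= 2, !anyNA(ratings))
  row_means <- rowMeans(ratings); col_means <- colMeans(ratings)
  grand <- mean(ratings)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_tot <- sum((ratings - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (msr <= 0 || ss_rows < 1e-12 * max(ss_tot, 1))
    stop("degenerate input: no variance across subjects")
  alpha <- 1 - conf_level

  icc_c <- (msr - mse) / (msr + (k - 1) * mse)
  fobs <- msr / mse
  fl <- fobs / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
  fu <- fobs * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
  ci_c <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))

  icc_a <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  a <- k * icc_a / (n * (1 - icc_a))
  b <- 1 + k * icc_a * (n - 1) / (n * (1 - icc_a))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f1 <- stats::qf(1 - alpha / 2, n - 1, v)
  f2 <- stats::qf(1 - alpha / 2, v, n - 1)
  lo_a <- n * (msr - f1 * mse) /
    (f1 * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi_a <- n * (f2 * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f2 * msr)
  list(consistency = list(icc = icc_c, ci_low = ci_c[1], ci_high = ci_c[2]),
       agreement = list(icc = icc_a, ci_low = lo_a, ci_high = hi_a),
       ms = c(rows = msr, cols = msc, error = mse), n = n, k = k)
}

#' Pairwise Pearson correlations with Bonferroni correction
#'
#' Two-tailed Pearson correlation for every pair of raters, with the family
#' alpha divided by the number of pairs (`choose(k, 2)`); with four raters
#' (three experts plus the model) this gives six pairs and a corrected alpha
#' of 0.05 / 6 = 0.0083.
#'
#' @param counts Numeric `n x k` matrix of per-image counts, one column per
#'   rater (named columns become pair labels).
#' @param family_alpha Family-wise error rate (default 0.05).
#' @return Data frame with one row per pair: `rater_a`, `rater_b`, `r`, `p`,
#'   `significant`; attribute `corrected_alpha`.
#' @export
pairwise_pearson_bonferroni <- function(counts, family_alpha = 0.05) {
  counts <- as.matrix(counts)
  k <- ncol(counts)
  stopifnot(k >= 2, nrow(counts) >= 3)
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("rater", seq_len(k))
  pairs <- utils::combn(k, 2)
  corrected <- family_alpha / ncol(pairs)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    if (stats::sd(counts[, a]) == 0 || stats::sd(counts[, b]) == 0)
      stop("undefined correlation: constant counts for rater pair ",
           colnames(counts)[a], " / ", colnames(counts)[b])
    ct <- stats::cor.test(counts[, a], counts[, b], method = "pearson",
                          alternative = "two.sided")
    data.frame(rater_a = colnames(counts)[a], rater_b = colnames(counts)[b],
               r = unname(ct$estimate), p = ct$p.value,
               significant = ct$p.value < corrected,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "corrected_alpha") <- corrected
  out
}

#' Correlation between model and consensus counts
#'
#' Pearson correlation (two-tailed), its p-value and the coefficient of
#' determination `r^2` between per-image automated counts and expert
#' consensus counts, with plot-ready pairs grouped by an optional condition
#' label (e.g. disease group).
#'
#' @param model_counts,consensus_counts Paired numeric vectors (`n >= 3`).
#' @param condition Optional grouping labels of the same length.
#' @return List with `r`, `p`, `r_squared`, `n`, and `data` (a data frame of
#'   the pairs and condition labels).
#' @export
count_correlation <- function(model_counts, consensus_counts,
                              condition = NULL) {
  stopifnot(length(model_counts) == length(consensus_counts),
            length(model_counts) >= 3)
  if (stats::sd(model_counts) == 0 || stats::sd(consensus_counts) == 0)
    stop("undefined correlation: constant counts")
  ct <- stats::cor.test(model_counts, consensus_counts, method = "pearson",
                        alternative = "two.sided")
  r <- unname(ct$estimate)
  list(r = r, p = ct$p.value, r_squared = r^2, n = length(model_counts),
       data = data.frame(model = model_counts, consensus = consensus_counts,
                         condition = if (is.null(condition)) NA_character_
                         else condition, stringsAsFactors = FALSE))
}
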