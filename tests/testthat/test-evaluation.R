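box_ann <- function(x, y, w, h, rater, z = 0L, class = "defect",
                    stack = "s") {
  data.frame(stack_id = stack, class = class, x_min = x, y_min = y,
             x_max = x + w, y_max = y + h, z = as.integer(z), rater = rater)
}

test_that("consensus requires agreement from at least two raters", {
  same <- rbind(box_ann(10, 10, 20, 20, "e1"), box_ann(10, 10, 20, 20, "e2"),
                box_ann(10, 10, 20, 20, "e3"))
  cg <- build_consensus(same)
  expect_equal(nrow(cg), 1)
  expect_equal(cg$support, 3)
  expect_equal(as.numeric(cg[1, c("x_min", "y_min", "x_max", "y_max")]),
               c(10, 10, 30, 30))
  # singleton annotations are excluded
  lone <- rbind(same, box_ann(100, 100, 20, 20, "e1"))
  expect_equal(nrow(build_consensus(lone)), 1)
  # but min_raters = 1 returns everything (upper-bound sanity)
  expect_equal(nrow(build_consensus(lone, min_raters = 1)), 2)
})

test_that("consensus linking respects the IoU threshold boundary", {
  # two 10 x 100 boxes sharing a fraction a of their width:
  # IoU = a / (2 - a); a = 0.32 -> 0.190, a = 0.35 -> 0.212
  pair <- function(a) rbind(
    box_ann(0, 0, 10, 100, "e1"),
    box_ann(10 * (1 - a), 0, 10, 100, "e2"))
  expect_equal(nrow(build_consensus(pair(0.32), iou_min = 0.2)), 0)
  expect_equal(nrow(build_consensus(pair(0.35), iou_min = 0.2)), 1)
})

test_that("consensus respects the z tolerance and rater-duplicate rule", {
  far <- rbind(box_ann(10, 10, 20, 20, "e1", z = 0),
               box_ann(10, 10, 20, 20, "e2", z = 2))
  expect_equal(nrow(build_consensus(far, z_tol = 1)), 0)
  expect_equal(nrow(build_consensus(far, z_tol = 2)), 1)
  # duplicate box from one rater: better-overlapping one is used
  dup <- rbind(box_ann(10, 10, 20, 20, "e1"),
               box_ann(10, 10, 20, 20, "e2"),
               box_ann(12, 12, 20, 20, "e2"))
  cg <- build_consensus(dup)
  expect_equal(nrow(cg), 1)
  expect_equal(attr(cg, "duplicates"), 1L)
  expect_equal(cg$x_min, 10)  # exact duplicate wins over the offset one
})

test_that("matching is one-to-one and conserves counts", {
  set.seed(51)
  for (i in 1:20) {
    fx <- random_eval_fixture(n_gt = 5, n_spurious = 5)
    m <- match_detections(fx$pred, fx$gt, iou_min = 0.2, z_tol = 1)
    expect_equal(m$tp + m$fn, nrow(fx$gt))
    expect_equal(m$tp + m$fp, nrow(fx$pred))
    expect_false(anyDuplicated(m$pairs$gt_idx) > 0)
    expect_false(anyDuplicated(m$pairs$pred_idx) > 0)
    expect_true(all(m$pairs$iou >= 0.2))
    # same TP count as the plain-loop reference
    expect_equal(m$tp, sum(match_ref(fx$pred, fx$gt, 0.2, 1)))
  }
})

test_that("z tolerance bounds matching", {
  gt <- box_ann(10, 10, 20, 20, "gt", z = 3)
  pred <- gt
  pred$rater <- NULL
  pred$confidence <- 0.9
  pred$z <- 5L
  m <- match_detections(pred, gt, iou_min = 0.2, z_tol = 1)
  expect_equal(c(m$tp, m$fp, m$fn), c(0, 1, 1))
  pred$z <- 4L
  m2 <- match_detections(pred, gt, iou_min = 0.2, z_tol = 1)
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(1, 0, 0))
})

test_that("precision, recall and F1 follow their defining formulas", {
  expect_equal(precision_recall_f1(1356, 173, 0)$precision, 1356 / 1529)
  prf <- precision_recall_f1(3, 1, 2)
  expect_equal(prf$precision, 0.75)
  expect_equal(prf$recall, 0.6)
  expect_equal(prf$f1, 2 * 0.75 * 0.6 / 1.35)
  expect_equal(precision_recall_f1(5, 0, 0),
               list(precision = 1, recall = 1, f1 = 1))
  expect_equal(precision_recall_f1(0, 3, 4)$f1, 0)
  expect_error(precision_recall_f1(-1, 0, 0))
  expect_error(precision_recall_f1(0, 0, 0))
})

test_that("average precision reproduces the trivial cases", {
  gt <- box_ann(10, 10, 20, 20, "gt")
  pred <- transform(gt[, names(gt) != "rater"], confidence = 0.9)
  expect_equal(average_precision(pred, gt)$ap, 1)
  expect_equal(average_precision(pred[0, ], gt)$ap, 0)
  expect_error(average_precision(pred, gt[0, ]), "undefined")
})

test_that("average precision equals the exhaustive threshold sweep", {
  set.seed(53)
  for (i in 1:200) {
    fx <- random_eval_fixture(n_gt = sample(2:6, 1),
                              n_spurious = sample(0:6, 1))
    ours <- average_precision(fx$pred, fx$gt, iou_min = 0.5, z_tol = 1)$ap
    ref <- ap_sweep_ref(fx$pred, fx$gt, iou_min = 0.5, z_tol = 1)
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("AP is stable under zero-confidence padding and monotone in IoU", {
  set.seed(54)
  fx <- random_eval_fixture(n_gt = 4, n_spurious = 4)
  base <- average_precision(fx$pred, fx$gt, iou_min = 0.5)$ap
  pad <- fx$pred[1, ]
  pad$confidence <- 0
  pad$x_min <- 190; pad$x_max <- 199  # matches nothing
  padded <- rbind(fx$pred, pad)
  expect_equal(average_precision(padded, fx$gt, iou_min = 0.5)$ap, base,
               tolerance = 1e-9)
  aps <- vapply(c(0.2, 0.5, 0.8), function(t)
    average_precision(fx$pred, fx$gt, iou_min = t)$ap, 1.0)
  expect_true(all(diff(aps) <= 1e-12))
})

test_that("weighted mAP is the class-frequency-weighted mean of APs", {
  expect_equal(weighted_map(c(a = 0.8, b = 0.6), c(a = 10, b = 10)), 0.7)
  expect_equal(weighted_map(c(defect = 0.5), c(defect = 99)), 0.5)
  w <- weighted_map(c(defect = 0.75, vesicle = 0.94),
                    c(defect = 234, vesicle = 21))
  expect_equal(w, (234 * 0.75 + 21 * 0.94) / 255)
  # bounded by the per-class extremes
  expect_true(w >= 0.75 && w <= 0.94)
  expect_error(weighted_map(c(a = 0.5), c(b = 3)))
})

test_that("evaluate_detections assembles a coherent report", {
  ph <- tiny_phantom(seed = 29)
  st <- render_scene(ph$scene)
  det <- run_inference(st, oracle_detector(ph$ground_truth),
                       window_size = 64, upsample_to = 128)
  er <- evaluate_detections(det, ph$ground_truth)
  expect_equal(er$precision, 1)
  expect_equal(er$recall, 1)
  expect_equal(er$f1, 1)
  expect_equal(unname(er$ap_per_class), c(1, 1), tolerance = 1e-9)
  expect_equal(er$weighted_map, 1)
  expect_output(print(er), "weighted mAP")
})

test_that("two-way single-measure ICC matches an independent implementation", {
  m64 <- matrix(c(9, 2, 5, 8,
                  6, 1, 3, 2,
                  8, 4, 6, 8,
                  7, 1, 2, 6,
                  10, 5, 6, 9,
                  6, 2, 4, 7), nrow = 6, byrow = TRUE)
  r <- icc_two_way_mixed_single(m64)
  expect_equal(r$consistency$icc, 0.7148407148407154, tolerance = 1e-6)
  # reference implementation prints its CIs at two decimals
  expect_lt(abs(r$consistency$ci_low - 0.34), 0.011)
  expect_lt(abs(r$consistency$ci_high - 0.95), 0.011)
  expect_equal(r$agreement$icc, 0.28976377952755916, tolerance = 1e-6)
  expect_lt(abs(r$agreement$ci_low - 0.02), 0.011)
  expect_lt(abs(r$agreement$ci_high - 0.76), 0.011)

  m63 <- matrix(c(7, 8, 7.5,
                  5, 5.5, 6,
                  9, 8.5, 9.5,
                  3, 4, 3.5,
                  6, 6.5, 6,
                  8, 7.5, 8.5), nrow = 6, byrow = TRUE)
  r2 <- icc_two_way_mixed_single(m63)
  expect_equal(r2$consistency$icc, 0.9531680440771348, tolerance = 1e-6)
  expect_equal(r2$agreement$icc, 0.9453551912568305, tolerance = 1e-6)
})

test_that("ICC hits its defining limits", {
  # identical raters, distinct subjects -> perfect reliability
  perfect <- matrix(rep(1:6, 3), 6, 3)
  expect_equal(icc_two_way_mixed_single(perfect)$consistency$icc, 1)
  # pure noise on identical subjects -> near-zero ICC with CI spanning 0
  set.seed(55)
  noise <- matrix(rnorm(60), 20, 3)
  rn <- icc_two_way_mixed_single(noise)
  expect_lt(abs(rn$consistency$icc), 0.5)
  expect_lt(rn$consistency$ci_low, 0)
  expect_gt(rn$consistency$ci_high, 0)
  expect_error(icc_two_way_mixed_single(matrix(5, 4, 3)), "degenerate")
})

test_that("pairwise Pearson applies the Bonferroni family correction", {
  set.seed(56)
  counts <- matrix(rnorm(4 * 30, mean = 50, sd = 10), 30, 4)
  colnames(counts) <- c("e1", "e2", "e3", "model")
  tab <- pairwise_pearson_bonferroni(counts)
  expect_equal(nrow(tab), 6)  # four raters -> six pairs
  expect_equal(attr(tab, "corrected_alpha"), 0.05 / 6)
  expect_equal(round(attr(tab, "corrected_alpha"), 4), 0.0083)
  # identical vectors correlate perfectly and significantly
  dup <- cbind(counts[, 1:3], e1copy = counts[, 1])
  tab2 <- pairwise_pearson_bonferroni(dup)
  row <- tab2[tab2$rater_a == "e1" & tab2$rater_b == "e1copy", ]
  expect_equal(row$r, 1)
  expect_true(row$significant)
  const <- counts; const[, 2] <- 7
  expect_error(pairwise_pearson_bonferroni(const), "constant")
})

test_that("count correlation reports r, p and r^2 consistently", {
  x <- c(3, 7, 9, 12, 15, 21)
  perfect <- count_correlation(x, x)
  expect_equal(perfect$r, 1)
  expect_equal(perfect$r_squared, 1)
  set.seed(57)
  y <- x + rnorm(6, 0, 2)
  cc <- count_correlation(x, y, condition = rep(c("AD", "CTE", "CTRL"), 2))
  expect_equal(cc$r_squared, cc$r^2, tolerance = 1e-12)
  expect_equal(nrow(cc$data), 6)
  expect_error(count_correlation(x, rep(1, 6)), "constant")
})
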