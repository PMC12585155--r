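test_that("iou computes intersection over union on half-open boxes", {
  expect_equal(iou(c(0, 0, 10, 10), c(0, 0, 10, 10)), 1)
  expect_equal(iou(c(0, 0, 10, 10), c(20, 20, 30, 30)), 0)
  expect_equal(iou(c(0, 0, 10, 10), c(5, 0, 15, 10)), 1 / 3)
  # symmetric
  set.seed(31)
  for (i in 1:20) {
    a <- as.numeric(random_boxes(1)[, 3:6]); b <- as.numeric(random_boxes(1)[, 3:6])
    expect_equal(iou(a, b), iou(b, a))
    expect_equal(iou(a, b), iou_ref(a, b))
  }
})

test_that("nms keeps the best of overlapping boxes and all disjoint ones", {
  two <- data.frame(stack_id = "s", class = "defect",
                    x_min = c(0, 0), y_min = c(0, 0),
                    x_max = c(10, 10), y_max = c(10, 10),
                    z = 0L, confidence = c(0.9, 0.8))
  out <- nms(two, 0.5)
  expect_equal(nrow(out), 1)
  expect_equal(out$confidence, 0.9)
  disj <- two
  disj[2, c("x_min", "x_max")] <- c(50, 60)
  expect_equal(nrow(nms(disj, 0.5)), 2)
})

test_that("nms agrees with the brute-force reference on random fixtures", {
  set.seed(33)
  for (trial in 1:200) {
    n <- sample(1:50, 1)
    det <- random_boxes(n)
    det$confidence <- runif(n)  # ties are vanishingly unlikely
    thr <- runif(1, 0.2, 0.7)
    a <- nms(det, thr)
    b <- nms_ref(det, thr)
    expect_equal(a[order(-a$confidence), "confidence"],
                 b[order(-b$confidence), "confidence"])
    expect_equal(as.matrix(a[order(-a$confidence), 3:6]),
                 as.matrix(b[order(-b$confidence), 3:6]),
                 ignore_attr = TRUE)
  }
})

test_that("chains require strictly consecutive planes", {
  mk <- function(zs) data.frame(stack_id = "s", class = "vesicle",
                                x_min = 10, y_min = 10, x_max = 20,
                                y_max = 20, z = as.integer(zs),
                                confidence = 0.9)
  one <- link_chains(mk(4))
  expect_equal(one$span, 1L)
  run <- link_chains(mk(c(3, 4, 5)))
  expect_equal(unique(run$chain_id), run$chain_id[1])
  expect_equal(run$span, rep(3L, 3))
  gap <- link_chains(mk(c(2, 4)))
  expect_equal(length(unique(gap$chain_id)), 2)
  expect_equal(gap$span, c(1L, 1L))
})

test_that("z-plane filter removes only long vesicle chains", {
  mk <- function(class, zs, x = 10) data.frame(
    stack_id = "s", class = class, x_min = x, y_min = 10, x_max = x + 10,
    y_max = 20, z = as.integer(zs), confidence = 0.9)
  for (span in 1:4) {
    det <- mk("vesicle", seq_len(span) - 1L)
    kept <- z_plane_filter(det)
    if (span <= 2) expect_equal(nrow(kept), span) else
      expect_equal(nrow(kept), 0)
  }
  # defects are never removed, whatever their span
  expect_equal(nrow(z_plane_filter(mk("defect", 0:4))), 5)
  # removal is monotone in span and removes all chain members
  mixed <- rbind(mk("vesicle", 0:3), mk("vesicle", 1, x = 100))
  kept <- z_plane_filter(mixed)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$x_min, 100)
})

test_that("phantom vesicle survives the z-filter while the axon is removed", {
  ph <- generate_phantom(n_defects = 0, n_vesicles = 1, n_transverse = 1,
                         shape = c(5, 128, 128), seed = 13,
                         noise = list(gaussian_sigma = 0, poisson_scale = 0))
  # oracle detections: ground truth plus the axon rings the detector would fire on
  axon <- ph$confounders
  axon$class <- "vesicle"
  bait <- rbind(ph$ground_truth, axon)
  st <- render_scene(ph$scene)
  det <- run_inference(st, oracle_detector(bait), window_size = 64,
                       upsample_to = 128)
  expect_equal(nrow(det), 1)
  expect_equal(det$class, "vesicle")
  expect_equal(det$z, ph$ground_truth$z[ph$ground_truth$class == "vesicle"])
})

test_that("sliding-window inference collapses duplicates to one detection", {
  ph <- tiny_phantom()
  st <- render_scene(ph$scene)
  det <- run_inference(st, oracle_detector(ph$ground_truth),
                       window_size = 64, upsample_to = 128)
  expect_equal(nrow(det), nrow(ph$ground_truth))
  m <- match_detections(det, ph$ground_truth, iou_min = 0.99, z_tol = 0)
  expect_equal(m$tp, nrow(ph$ground_truth))
  expect_gt(attr(det, "windows_processed"), 0)
  expect_equal(attr(det, "windows_failed"), 0)
})

test_that("blank stacks yield empty detection sets", {
  st <- zstack(array(0, c(2, 128, 128, 3)))
  det <- run_inference(st, baseline_blob_detector(), window_size = 64,
                       upsample_to = 128)
  expect_equal(nrow(det), 0)
})

test_that("detector failures are logged and skipped, not fatal", {
  flaky <- list(predict = function(img, w) {
    if (w$x0 == 0 && w$y0 == 0) stop("boom")
    detection_df()
  }, conf_threshold = 0)
  st <- zstack(array(0.1, c(1, 64, 64, 3)))
  expect_warning(det <- run_inference(st, flaky, window_size = 64,
                                      upsample_to = 64), "boom")
  expect_equal(attr(det, "windows_failed"), 1L)
})

test_that("inference is equivariant to stride-sized translations", {
  mk <- function(cx) phantom_scene(
    defects = list(defect_spec("vesicle", c(cx, 80), 0, extent = 8)),
    shape = c(1, 160, 160), z_focus = 0,
    noise = list(gaussian_sigma = 0, poisson_scale = 0))
  stride <- 32L
  st <- render_scene(mk(60))
  st2 <- render_scene(mk(60 + stride))
  d1 <- run_inference(st, baseline_blob_detector(), window_size = 64,
                      upsample_to = 128)
  d2 <- run_inference(st2, baseline_blob_detector(), window_size = 64,
                      upsample_to = 128)
  expect_equal(nrow(d1), nrow(d2))
  expect_equal(d2$x_min, d1$x_min + stride, tolerance = 0.05)
  expect_equal(d2$y_min, d1$y_min, tolerance = 0.05)
})

test_that("density heatmap counts defect centers per window", {
  expect_true(all(density_heatmap(detection_df(), 200, 200,
                                  size = 50)$counts == 0))
  one <- data.frame(stack_id = "s", class = "defect", x_min = 70, y_min = 70,
                    x_max = 80, y_max = 80, z = 0L, confidence = 0.9)
  hg <- density_heatmap(one, 200, 200, size = 50)
  expect_gte(max(hg$counts), 1)
  # non-overlapping partition conserves the center count
  hg0 <- density_heatmap(one, 200, 200, size = 50, overlap_fraction = 0)
  expect_equal(sum(hg0$counts), 1)
  # vesicles are not counted in the defect heatmap
  one$class <- "vesicle"
  expect_equal(sum(density_heatmap(one, 200, 200, size = 50)$counts), 0)
})

test_that("uniform detections give the Monte-Carlo expected density", {
  set.seed(35)
  n <- 2000
  det <- data.frame(stack_id = "s", class = "defect",
                    x_min = runif(n, 0, 630), y_min = runif(n, 0, 630),
                    z = 0L, confidence = 1)
  det$x_max <- det$x_min + 10; det$y_max <- det$y_min + 10
  hg <- density_heatmap(det, 640, 640, size = 64, overlap_fraction = 0)
  expected <- n * 64^2 / 640^2
  expect_lt(abs(mean(hg$counts) - expected), 3 * sqrt(expected))
})

test_that("heatmap overlay renders to an RGB image", {
  ph <- generate_phantom(n_defects = 1, n_vesicles = 0, shape = c(2, 64, 64),
                         seed = 3,
                         noise = list(gaussian_sigma = 0, poisson_scale = 0))
  st <- render_scene(ph$scene)
  det <- run_inference(st, oracle_detector(ph$ground_truth),
                       window_size = 32, upsample_to = 64)
  hg <- density_heatmap(det, 64, 64, size = 32)
  img <- render_heatmap(hg, st)
  expect_equal(dim(img), c(64, 64, 3))
  expect_true(all(img >= 0 & img <= 1))
  path <- withr::local_tempfile(fileext = ".png")
  render_heatmap(hg, st, path = path)
  expect_true(file.exists(path))
})
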