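# Independent reference implementations used to cross-check the package.

# Numeric Jones-matrix oracle for the crossed-circular-polarizer chain:
# LP(0 deg) -> QWP(gamma, +45 deg) -> retarder(delta, theta) ->
# QWP(gamma, -45 deg) -> LP(90 deg), evaluated by 2x2 complex products.
jones_oracle <- function(delta, theta, gamma, i0 = 1) {
  rot <- function(a) matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  ret <- function(g, phi)
    rot(phi) %*% diag(c(exp(-1i * g / 2), exp(1i * g / 2))) %*% rot(-phi)
  lp_v <- matrix(c(0, 0, 0, 1), 2, 2)
  e <- lp_v %*% ret(gamma, -pi / 4) %*% ret(delta, theta) %*%
    ret(gamma, pi / 4) %*% matrix(c(sqrt(i0), 0), 2, 1)
  sum(Mod(e)^2)
}

# Scalar IoU computed with an independent formulation (edge coordinates).
iou_ref <- function(a, b) {
  w <- min(a[3], b[3]) - max(a[1], b[1])
  h <- min(a[4], b[4]) - max(a[2], b[2])
  if (w <= 0 || h <= 0) return(0)
  ia <- w * h
  ia / ((a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - ia)
}

# Plain-loop greedy NMS reference: keep the best remaining box, drop
# overlaps, repeat.
nms_ref <- function(det, thr) {
  det <- det[order(-det$confidence), ]
  kept <- list()
  while (nrow(det) > 0) {
    top <- det[1, ]
    kept[[length(kept) + 1]] <- top
    if (nrow(det) == 1) break
    rest <- det[-1, , drop = FALSE]
    ok <- vapply(seq_len(nrow(rest)), function(i) {
      iou_ref(as.numeric(top[c("x_min", "y_min", "x_max", "y_max")]),
              as.numeric(rest[i, c("x_min", "y_min", "x_max", "y_max")])) < thr
    }, TRUE)
    det <- rest[ok, , drop = FALSE]
  }
  out <- do.call(rbind, kept)
  rownames(out) <- NULL
  out
}

# Plain-loop greedy matcher (descending confidence, best IoU first) giving
# per-prediction TP flags at a fixed IoU threshold.
match_ref <- function(pred, gt, iou_min, z_tol = 1) {
  ord <- order(-pred$confidence)
  taken <- logical(nrow(gt))
  tp <- logical(nrow(pred))
  for (i in ord) {
    best <- 0; bestj <- 0
    for (j in seq_len(nrow(gt))) {
      if (taken[j] || gt$class[j] != pred$class[i]) next
      if (abs(gt$z[j] - pred$z[i]) > z_tol) next
      v <- iou_ref(as.numeric(pred[i, c("x_min", "y_min", "x_max", "y_max")]),
                   as.numeric(gt[j, c("x_min", "y_min", "x_max", "y_max")]))
      if (v >= iou_min && v > best) { best <- v; bestj <- j }
    }
    if (bestj > 0) { taken[bestj] <- TRUE; tp[i] <- TRUE }
  }
  tp
}

# All-point AP by exhaustive confidence-threshold sweep: at every threshold
# compute (recall, precision), then integrate the running-max precision
# envelope over recall with a plain loop.
ap_sweep_ref <- function(pred, gt, iou_min = 0.5, z_tol = 1) {
  if (nrow(pred) == 0) return(0)
  tp <- match_ref(pred, gt, iou_min, z_tol)
  ths <- sort(unique(pred$confidence), decreasing = TRUE)
  pts <- t(vapply(ths, function(t) {
    sel <- pred$confidence >= t
    ntp <- sum(tp[sel]); np <- sum(sel)
    c(r = ntp / nrow(gt), p = if (np > 0) ntp / np else 0)
  }, c(r = 0, p = 0)))
  pts <- pts[order(pts[, "r"]), , drop = FALSE]
  ap <- 0; r_prev <- 0
  for (i in seq_len(nrow(pts))) {
    env <- max(pts[i:nrow(pts), "p"])
    ap <- ap + (pts[i, "r"] - r_prev) * env
    r_prev <- pts[i, "r"]
  }
  unname(ap)
}

# Random detection frame of one class on one plane.
random_boxes <- function(n, class = "defect", z = 0L, size = 200) {
  if (n == 0) return(detection_df())
  x0 <- runif(n, 0, size - 30)
  y0 <- runif(n, 0, size - 30)
  w <- runif(n, 8, 30)
  h <- runif(n, 8, 30)
  data.frame(stack_id = "s", class = class, x_min = x0, y_min = y0,
             x_max = pmin(x0 + w, size), y_max = pmin(y0 + h, size),
             z = as.integer(z), confidence = runif(n),
             stringsAsFactors = FALSE)
}

# Random prediction/ground-truth fixture: jittered copies of the ground
# truth plus spurious boxes, with random confidences.
random_eval_fixture <- function(n_gt = 5, n_spurious = 5, size = 200) {
  gt <- random_boxes(n_gt, size = size)
  gt$confidence <- NULL
  gt$rater <- "gt"
  jit <- gt
  jit$rater <- NULL
  d <- runif(n_gt, -3, 3)
  jit$x_min <- jit$x_min + d; jit$x_max <- jit$x_max + d
  jit$y_min <- jit$y_min + runif(n_gt, -3, 3)
  jit$y_max <- jit$y_min + (gt$y_max - gt$y_min)
  jit$confidence <- runif(n_gt, 0.5, 1)
  sp <- random_boxes(n_spurious, size = size)
  sp$confidence <- runif(n_spurious, 0, 0.8)
  pred <- rbind(jit, sp)
  rownames(pred) <- NULL
  list(pred = pred, gt = gt)
}

# Tiny phantom used across tests: a couple of fibers, one defect, one
# vesicle, optionally one transverse axon; noise off for geometric checks.
tiny_phantom <- function(n_transverse = 0, shape = c(5, 128, 128), seed = 7,
                         noise = list(gaussian_sigma = 0, poisson_scale = 0)) {
  generate_phantom(n_defects = 2, n_vesicles = 2,
                   n_transverse = n_transverse, n_fibers = 6,
                   shape = shape, seed = seed, noise = noise)
}
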