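#' Baseline blob detector plugin
#'
#' A reference detector so the inference pipeline can be exercised without
#' trained network weights. Bright anomalies are segmented on the green
#' channel of the upsampled window (Gaussian smoothing, intensity threshold,
#' connected components); compact, near-circular components are labeled
#' `vesicle` and elongated or irregular ones `defect`. Confidence is the
#' peak smoothed intensity of the component, clipped to `[0, 1]`. Fully
#' deterministic.
#'
#' @param conf_threshold Minimum confidence kept by [run_inference()].
#' @param sigma Smoothing sigma in upsampled-window pixels.
#' @param intensity_threshold Segmentation threshold on smoothed intensity.
#' @param min_area Minimum component area (upsampled px^2).
#' @param ecc_vesicle Eccentricity below which a component is a vesicle.
#' @return A detector plugin: list with `predict(image, window)`,
#'   `conf_threshold` and `name`.
#' @export
baseline_blob_detector <- function(conf_threshold = 0.2, sigma = 5,
                                   intensity_threshold = 0.3,
                                   min_area = 120, ecc_vesicle = 0.8) {
  predict <- function(image, window) {
    g <- if (length(dim(image)) == 3) image[, , min(2, dim(image)[3])] else
      image
    sm <- EBImage::gblur(g, sigma = sigma)
    mask <- sm > intensity_threshold
    if (!any(mask)) return(detection_df())
    lab <- EBImage::bwlabel(mask)
    n <- max(lab)
    out <- list()
    for (k in seq_len(n)) {
      idx <- which(lab == k, arr.ind = TRUE)
      if (nrow(idx) < min_area) next
      rows <- idx[, 1]; cols <- idx[, 2]
      # second central moments -> eccentricity of the equivalent ellipse
      cc <- stats::cov(cbind(cols, rows))
      ev <- eigen(cc, symmetric = TRUE, only.values = TRUE)$values
      ecc <- if (ev[1] <= 0) 0 else sqrt(max(0, 1 - ev[2] / ev[1]))
      cls <- if (ecc < ecc_vesicle) "vesicle" else "defect"
      out[[length(out) + 1]] <- data.frame(
        stack_id = "window", class = cls,
        x_min = min(cols) - 1, y_min = min(rows) - 1,
        x_max = max(cols), y_max = max(rows),
        z = window$z,
        confidence = min(1, max(sm[lab == k])),
        stringsAsFactors = FALSE)
    }
    bind_rows_(out, detection_df())
  }
  list(predict = predict, conf_threshold = conf_threshold,
       name = "baseline_blob")
}

#' Oracle detector plugin
#'
#' Emits the planted ground-truth boxes of a phantom for every window that
#' fully contains them, at fixed confidence. Used to validate the geometry
#' of the sliding-window pipeline (window mapping, NMS duplicate collapse,
#' z-plane filtering) independently of any real detector.
#'
#' @param gt Annotation data frame of planted objects (global coordinates).
#' @param confidence Confidence attached to every emitted box.
#' @return A detector plugin (see [baseline_blob_detector()]).
#' @export
oracle_detector <- function(gt, confidence = 0.99) {
  force(gt); force(confidence)
  predict <- function(image, window) {
    hit <- gt$z == window$z &
      gt$x_min >= window$x0 & gt$x_max <= window$x0 + window$size &
      gt$y_min >= window$y0 & gt$y_max <= window$y0 + window$size
    sub <- gt[hit, , drop = FALSE]
    if (nrow(sub) == 0) return(detection_df())
    sub$confidence <- confidence
    sub$rater <- NULL
    map_to_window(sub[, c("stack_id", "class", "x_min", "y_min", "x_max",
                          "y_max", "z", "confidence")], window)
  }
  list(predict = predict, conf_threshold = 0, name = "oracle")
}
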