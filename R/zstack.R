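#' Volumetric image stack
#'
#' Container for a CCP-BRM z-stack: a `(n_z, height, width, n_channels)`
#' intensity array plus acquisition metadata. Channels are ordered R, G, B
#' for `channel_mode = "rgb"`; `"ggg"` marks a three-channel stack whose
#' channels are identical copies of the green channel; `"gray"` is a single
#' channel.
#'
#' @param voxels Numeric array; 3-d `(n_z, h, w)` input is promoted to a
#'   single-channel 4-d array. Intensities must be >= 0.
#' @param pixel_size_um Lateral pixel size (um/px).
#' @param z_step_um Focal step between planes (um).
#' @param channel_mode One of `"rgb"`, `"gray"`, `"ggg"`.
#' @return An object of class `zstack`.
#' @export
zstack <- function(voxels, pixel_size_um = 0.226, z_step_um = 1.3,
                   channel_mode = c("rgb", "gray", "ggg")) {
  if (length(dim(voxels)) == 3) dim(voxels) <- c(dim(voxels), 1L)
  stopifnot(length(dim(voxels)) == 4)
  nc <- dim(voxels)[4]
  if (length(channel_mode) > 1)  # unspecified: infer from channel count
    channel_mode <- if (nc == 1L) "gray" else "rgb"
  channel_mode <- match.arg(channel_mode, c("rgb", "gray", "ggg"))
  if (!nc %in% c(1L, 3L)) stop("n_channels must be 1 or 3")
  if (channel_mode %in% c("rgb", "ggg") && nc != 3L)
    stop(sprintf("channel_mode '%s' requires 3 channels", channel_mode))
  if (channel_mode == "gray" && nc != 1L)
    stop("channel_mode 'gray' requires 1 channel")
  if (dim(voxels)[1] < 1) stop("n_z must be >= 1")
  if (min(voxels) < 0) stop("intensities must be >= 0")
  stopifnot(pixel_size_um > 0, z_step_um > 0)
  structure(list(voxels = voxels, pixel_size_um = pixel_size_um,
                 z_step_um = z_step_um, channel_mode = channel_mode),
            class = "zstack")
}

#' @export
print.zstack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<zstack> %d plane(s) x %d x %d px, %d channel(s) [%s], %.3g um/px, %.3g um z-step\n",
              d[1], d[2], d[3], d[4], x$channel_mode, x$pixel_size_um,
              x$z_step_um))
  invisible(x)
}

#' @export
dim.zstack <- function(x) dim(x$voxels)

#' Read / write a z-stack as multi-page TIFF
#'
#' One TIFF page per z-plane (RGB or single-channel). Intensities are stored
#' as 16-bit samples; integer-valued stacks in `[0, 65535]` round-trip
#' losslessly. Acquisition metadata (pixel size, z-step, channel mode, and
#' the intensity scale used for quantization) is stored in a JSON sidecar
#' `<path>.json`, written and read automatically.
#'
#' @param path TIFF file path.
#' @param stack A [zstack()].
#' @return `read_stack()` returns a [zstack()]; `write_stack()` returns
#'   `path` invisibly.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- lapply(pages, function(p) dim(p)[1:2])
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1)
    stop("ragged TIFF: pages have mixed shapes")
  nch <- vapply(pages, function(p) if (length(dim(p)) == 3) dim(p)[3] else 1L,
                1L)
  if (length(unique(nch)) != 1) stop("ragged TIFF: pages have mixed channels")
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else
    list(pixel_size_um = 0.226, z_step_um = 1.3,
         channel_mode = if (nch[1] == 3) "rgb" else "gray", scale = 65535)
  nz <- length(pages); h <- dims[[1]][1]; w <- dims[[1]][2]
  vox <- array(0, c(nz, h, w, nch[1]))
  for (z in seq_len(nz)) {
    p <- pages[[z]]
    if (length(dim(p)) == 2) dim(p) <- c(dim(p), 1L)
    vox[z, , , ] <- p
  }
  vox <- round(vox * 65535) / 65535 * meta$scale
  zstack(vox, pixel_size_um = meta$pixel_size_um, z_step_um = meta$z_step_um,
         channel_mode = meta$channel_mode)
}

#' @rdname read_stack
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "zstack"))
  d <- dim(stack$voxels)
  scale <- max(stack$voxels, 1e-12)
  # integer-valued stacks (e.g. 8/16-bit camera data) keep their own scale so
  # that value / 65535-quantization round-trips exactly
  if (all(stack$voxels == round(stack$voxels)) && scale <= 65535)
    scale <- 65535
  pages <- lapply(seq_len(d[1]), function(z) {
    p <- stack$voxels[z, , , , drop = TRUE]
    if (length(dim(p)) < 2) dim(p) <- d[2:3]
    p / scale
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  jsonlite::write_json(
    list(pixel_size_um = stack$pixel_size_um, z_step_um = stack$z_step_um,
         channel_mode = stack$channel_mode, scale = scale),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Green-channel replication (RGB to GGG)
#'
#' Converts an RGB stack to grayscale format while keeping the three-channel
#' structure detectors expect: the green channel is duplicated into the red
#' and blue channels. Used to train/evaluate on grayscale imagery with
#' RGB-shaped models.
#'
#' @param stack An RGB [zstack()].
#' @return A [zstack()] with `channel_mode = "ggg"` and three identical
#'   channels equal to the input green channel.
#' @export
rgb_to_ggg <- function(stack) {
  stopifnot(inherits(stack, "zstack"))
  if (stack$channel_mode == "gray")
    stop("rgb_to_ggg requires a 3-channel stack, got 'gray'")
  vox <- stack$voxels
  g <- vox[, , , 2, drop = FALSE]
  out <- array(g, dim = dim(vox)[1:3])
  out <- array(rep(out, 3), c(dim(vox)[1:3], 3))
  zstack(out, pixel_size_um = stack$pixel_size_um,
         z_step_um = stack$z_step_um, channel_mode = "ggg")
}

#' Focus-stacked (maximum-intensity) projection
#'
#' @param stack A [zstack()].
#' @return `(h, w, c)` array of per-pixel maxima over z.
#' @export
max_projection <- function(stack) {
  stopifnot(inherits(stack, "zstack"))
  apply(stack$voxels, c(2, 3, 4), max)
}
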