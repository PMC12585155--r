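#' Fiber segment for a synthetic scene
#'
#' A myelinated fiber is modelled as an anti-aliased stroke of physical
#' thickness `thickness_d` along a polyline `path`; the in-plane optic-axis
#' orientation at a pixel is the tangent direction of the nearest path
#' segment, reduced to `[0, pi)`.
#'
#' @param path Numeric matrix (n x 2) of ordered (x, y) points in 0-based
#'   pixel coordinates; at least two points.
#' @param thickness_d Fiber thickness in micrometers (> 0).
#' @param delta_n Birefringence `n_e - n_o`; a scalar, or a length-3 vector
#'   giving per-channel (R, G, B) values when fiber dispersion matters.
#' @return An object of class `fiber_segment`.
#' @export
fiber_segment <- function(path, thickness_d = 1, delta_n = 0.12) {
  path <- as.matrix(path)
  stopifnot(ncol(path) == 2, nrow(path) >= 2)
  if (thickness_d <= 0) stop("thickness_d must be > 0")
  if (any(delta_n < 0)) stop("delta_n must be >= 0")
  if (!length(delta_n) %in% c(1, 3))
    stop("delta_n must have length 1 or 3 (per RGB channel)")
  structure(list(path = path, thickness_d = thickness_d, delta_n = delta_n),
            class = "fiber_segment")
}

.defect_kinds <- c("break", "swelling", "blebbing", "vesicle",
                   "transverse_axon")

#' Planted defect, vesicle or transverse-axon confounder
#'
#' `break`, `swelling` and `blebbing` modify the thickness of the fiber layer
#' (a retardance gap or a local thickness multiplier) and are rendered in
#' every plane, blurred by defocus like the fibers. A `vesicle` is a bright
#' birefringent ring that is sharp in exactly one z-plane. A
#' `transverse_axon` is the same ring replicated over `span >= 3` consecutive
#' planes — the confounder targeted by the z-plane filter.
#'
#' @param kind One of `"break"`, `"swelling"`, `"blebbing"`, `"vesicle"`,
#'   `"transverse_axon"`.
#' @param center Length-2 (x, y) center in 0-based pixels.
#' @param z_center 0-based plane index.
#' @param extent Characteristic diameter in pixels (> 0).
#' @param magnitude Multiplicative retardance/thickness modifier for fiber
#'   defects; equivalent ring thickness in micrometers for `vesicle` and
#'   `transverse_axon`.
#' @param span Number of consecutive planes a `transverse_axon` occupies
#'   (>= 3); ignored for other kinds.
#' @return An object of class `defect_spec`.
#' @export
defect_spec <- function(kind, center, z_center, extent = 10, magnitude = 2,
                        span = 3) {
  kind <- match.arg(kind, .defect_kinds)
  stopifnot(length(center) == 2, extent > 0, magnitude >= 0, z_center >= 0)
  if (kind == "transverse_axon" && span < 3)
    stop("a transverse_axon must span >= 3 consecutive z-planes")
  structure(list(kind = kind, center = as.numeric(center),
                 z_center = as.integer(z_center), extent = extent,
                 magnitude = magnitude,
                 span = if (kind == "transverse_axon") as.integer(span) else 1L),
            class = "defect_spec")
}

#' Parametric synthetic scene with exact ground truth
#'
#' Describes a fiber-rich cortical-tissue phantom: fibers, planted defects
#' and confounders, stack geometry, defocus and noise. The ground truth
#' (class, box, z-index of every planted object) is derivable from the scene
#' alone, without rendering.
#'
#' @param fibers List of [fiber_segment()] objects.
#' @param defects List of [defect_spec()] objects, all inside image bounds.
#' @param shape Integer vector `c(n_z, height, width)`; `n_z >= 1`.
#' @param pixel_size_um Lateral pixel size (um/px).
#' @param z_step_um Focal step between planes (um); 1.3 um matches typical
#'   volumetric CCP-BRM acquisition.
#' @param z_focus 0-based index of the in-focus plane for the fiber layer;
#'   defaults to the middle plane.
#' @param noise List with `gaussian_sigma` (additive read noise as a fraction
#'   of `i0`) and `poisson_scale` (photons per intensity unit for shot noise;
#'   0 disables).
#' @param defocus_sigma_per_um Growth rate of the Gaussian defocus blur
#'   (px of sigma per um of defocus).
#' @param seed Integer seed controlling the noise realization.
#' @return An object of class `phantom_scene`.
#' @export
phantom_scene <- function(fibers = list(), defects = list(),
                          shape = c(5L, 256L, 256L),
                          pixel_size_um = 0.226, z_step_um = 1.3,
                          z_focus = (shape[1] - 1L) %/% 2L,
                          noise = list(gaussian_sigma = 0.02,
                                       poisson_scale = 0),
                          defocus_sigma_per_um = 0.6, seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, shape[1] >= 1, shape[2] >= 1, shape[3] >= 1,
            pixel_size_um > 0, z_step_um > 0,
            z_focus >= 0, z_focus < shape[1])
  for (f in fibers) stopifnot(inherits(f, "fiber_segment"))
  for (d in defects) {
    stopifnot(inherits(d, "defect_spec"))
    if (d$center[1] < 0 || d$center[1] >= shape[3] ||
        d$center[2] < 0 || d$center[2] >= shape[2])
      stop("defect center outside image bounds")
    if (d$z_center >= shape[1]) stop("defect z_center outside stack")
    if (d$kind == "transverse_axon" && d$z_center + d$span > shape[1])
      stop("transverse_axon span exceeds stack depth")
  }
  if (is.null(noise$gaussian_sigma)) noise$gaussian_sigma <- 0
  if (is.null(noise$poisson_scale)) noise$poisson_scale <- 0
  structure(list(fibers = fibers, defects = defects, shape = shape,
                 pixel_size_um = pixel_size_um, z_step_um = z_step_um,
                 z_focus = as.integer(z_focus), noise = noise,
                 defocus_sigma_per_um = defocus_sigma_per_um,
                 seed = as.integer(seed)),
            class = "phantom_scene")
}

#' Ground truth of a phantom scene
#'
#' Exact bounding boxes for the planted defects and vesicles; transverse
#' axons are returned separately as known confounders, one row per occupied
#' plane, because they are deliberate false-positive bait rather than ground
#' truth.
#'
#' @param scene A [phantom_scene()].
#' @param margin Pixels added around `extent / 2` when forming boxes.
#' @param stack_id Identifier stored in the `stack_id` column.
#' @return List with `ground_truth` and `confounders` annotation data frames
#'   (columns `stack_id`, `class`, `x_min`, `y_min`, `x_max`, `y_max`, `z`,
#'   `rater`).
#' @export
scene_ground_truth <- function(scene, margin = 2, stack_id = "phantom") {
  stopifnot(inherits(scene, "phantom_scene"))
  gt <- list(); cf <- list()
  for (d in scene$defects) {
    half <- d$extent / 2 + margin
    row <- data.frame(stack_id = stack_id,
                      class = if (d$kind %in% c("vesicle", "transverse_axon"))
                        "vesicle" else "defect",
                      x_min = d$center[1] - half, y_min = d$center[2] - half,
                      x_max = d$center[1] + half, y_max = d$center[2] + half,
                      z = d$z_center, rater = "phantom",
                      stringsAsFactors = FALSE)
    if (d$kind == "transverse_axon") {
      rows <- row[rep(1, d$span), ]
      rows$z <- d$z_center + seq_len(d$span) - 1L
      rows$class <- "transverse_axon"
      cf[[length(cf) + 1]] <- rows
    } else {
      gt[[length(gt) + 1]] <- row
    }
  }
  empty <- annotation_df()
  list(ground_truth = if (length(gt)) do.call(rbind, gt) else empty,
       confounders = if (length(cf)) do.call(rbind, cf) else
         transform(empty, class = character(0)))
}

## ---- rasterization ---------------------------------------------------------

# Thickness (um) and orientation (rad) maps of the fiber layer.
# Pixel centers sit at (x + 0.5, y + 0.5) in 0-based coordinates.
rasterize_fibers <- function(scene) {
  h <- scene$shape[2]; w <- scene$shape[3]
  d_map <- matrix(0, h, w)
  theta_map <- matrix(0, h, w)
  dn_r <- matrix(0, h, w); dn_g <- matrix(0, h, w); dn_b <- matrix(0, h, w)
  best <- matrix(Inf, h, w)  # distance to nearest stroke centerline
  for (f in scene$fibers) {
    halfw <- (f$thickness_d / scene$pixel_size_um) / 2
    dn <- if (length(f$delta_n) == 3) f$delta_n else rep(f$delta_n, 3)
    p <- f$path
    for (i in seq_len(nrow(p) - 1)) {
      a <- p[i, ]; b <- p[i + 1, ]
      v <- b - a; len2 <- sum(v^2)
      if (len2 == 0) next
      th <- atan2(v[2], v[1]) %% pi
      x0 <- max(0, floor(min(a[1], b[1]) - halfw - 2))
      x1 <- min(w - 1, ceiling(max(a[1], b[1]) + halfw + 2))
      y0 <- max(0, floor(min(a[2], b[2]) - halfw - 2))
      y1 <- min(h - 1, ceiling(max(a[2], b[2]) + halfw + 2))
      if (x1 < x0 || y1 < y0) next
      cols <- (x0:x1) + 1L; rows <- (y0:y1) + 1L
      px <- matrix((x0:x1) + 0.5, length(rows), length(cols), byrow = TRUE)
      py <- matrix((y0:y1) + 0.5, length(rows), length(cols))
      t_ <- pmin(1, pmax(0, ((px - a[1]) * v[1] + (py - a[2]) * v[2]) / len2))
      dist <- sqrt((px - (a[1] + t_ * v[1]))^2 + (py - (a[2] + t_ * v[2]))^2)
      cov <- pmin(1, pmax(0, halfw + 0.5 - dist))
      dsub <- f$thickness_d * cov
      sub <- cbind(rep(rows, length(cols)), rep(cols, each = length(rows)))
      upd <- dist < best[sub] & cov > 0
      if (any(upd)) {
        s <- sub[upd, , drop = FALSE]
        best[s] <- dist[upd]
        theta_map[s] <- th
        dn_r[s] <- dn[1]; dn_g[s] <- dn[2]; dn_b[s] <- dn[3]
      }
      grow <- dsub > d_map[sub]
      if (any(grow)) d_map[sub[grow, , drop = FALSE]] <- dsub[grow]
    }
  }
  list(d_map = d_map, theta_map = theta_map,
       dn = list(r = dn_r, g = dn_g, b = dn_b))
}

# Apply break / swelling / blebbing thickness modifiers to the fiber layer.
apply_fiber_defects <- function(ras, scene) {
  h <- scene$shape[2]; w <- scene$shape[3]
  for (d in scene$defects) {
    if (!d$kind %in% c("break", "swelling", "blebbing")) next
    r0 <- d$extent / 2
    x0 <- max(0, floor(d$center[1] - r0 - 2))
    x1 <- min(w - 1, ceiling(d$center[1] + r0 + 2))
    y0 <- max(0, floor(d$center[2] - r0 - 2))
    y1 <- min(h - 1, ceiling(d$center[2] + r0 + 2))
    cols <- (x0:x1) + 1L; rows <- (y0:y1) + 1L
    px <- matrix((x0:x1) + 0.5, length(rows), length(cols), byrow = TRUE)
    py <- matrix((y0:y1) + 0.5, length(rows), length(cols))
    r <- sqrt((px - d$center[1])^2 + (py - d$center[2])^2)
    if (d$kind == "break") {
      # retardance gap: thickness suppressed inside the disc
      mult <- 1 - pmin(1, pmax(0, r0 + 0.5 - r))
    } else {
      # local thickness bump; blebbing is sharper than swelling
      sig <- if (d$kind == "swelling") r0 / 1.5 else r0 / 2.5
      mult <- 1 + (d$magnitude - 1) * exp(-r^2 / (2 * sig^2))
    }
    ras$d_map[rows, cols] <- ras$d_map[rows, cols] * mult
  }
  ras
}

# Intensity contribution of a birefringent ring (vesicle or transverse axon
# seen end-on): tangential optic axis, Gaussian radial thickness profile.
ring_intensity <- function(d, scene, optics, gammas, channel) {
  h <- scene$shape[2]; w <- scene$shape[3]
  out <- matrix(0, h, w)
  r0 <- d$extent / 2
  x0 <- max(0, floor(d$center[1] - r0 - 3))
  x1 <- min(w - 1, ceiling(d$center[1] + r0 + 3))
  y0 <- max(0, floor(d$center[2] - r0 - 3))
  y1 <- min(h - 1, ceiling(d$center[2] + r0 + 3))
  cols <- (x0:x1) + 1L; rows <- (y0:y1) + 1L
  px <- matrix((x0:x1) + 0.5, length(rows), length(cols), byrow = TRUE)
  py <- matrix((y0:y1) + 0.5, length(rows), length(cols))
  dx <- px - d$center[1]; dy <- py - d$center[2]
  r <- sqrt(dx^2 + dy^2)
  thick <- d$magnitude * exp(-(r - r0 * 0.7)^2 / (2 * (r0 / 3)^2))
  theta <- (atan2(dy, dx) + pi / 2) %% pi
  lam <- switch(channel, r = optics$lambda_r, g = optics$lambda_g,
                b = optics$lambda_b)
  delta <- retardance(pmax(thick, 1e-9), 0.12, lam)
  out[rows, cols] <- ccp_intensity(delta, theta, gammas[[channel]],
                                   optics$i0) * (thick > 1e-3)
  out
}

## ---- rendering -------------------------------------------------------------

#' Render a phantom scene to an RGB z-stack
#'
#' Forward-models RGB CCP-BRM image formation: per pixel and channel the
#' local retardance follows from the rasterized thickness/birefringence maps
#' ([retardance()]), the channel QWP retardance from [qwp_retardance()], and
#' the transmitted intensity from [ccp_intensity()]. Planes away from the
#' focus plane receive Gaussian defocus blur with
#' `sigma = defocus_sigma_per_um * |z - z_focus| * z_step_um`; vesicles and
#' transverse axons are composited sharply into their own planes (they sit at
#' their own focal depth); read/shot noise is added last under the scene
#' seed, so rendering is bit-reproducible.
#'
#' @param scene A [phantom_scene()].
#' @param optics An [optical_config()].
#' @return A [zstack()] with `channel_mode = "rgb"` and intensities in
#'   `[0, i0]`.
#' @export
render_scene <- function(scene, optics = optical_config()) {
  stopifnot(inherits(scene, "phantom_scene"), inherits(optics, "optical_config"))
  nz <- scene$shape[1]; h <- scene$shape[2]; w <- scene$shape[3]
  gammas <- as.list(channel_gammas(optics))
  ras <- apply_fiber_defects(rasterize_fibers(scene), scene)

  base <- array(0, c(h, w, 3))
  chans <- c("r", "g", "b")
  lams <- c(optics$lambda_r, optics$lambda_g, optics$lambda_b)
  for (ci in 1:3) {
    delta <- retardance(pmax(ras$d_map, 1e-9), 1, lams[ci]) *
      ras$dn[[chans[ci]]]
    base[, , ci] <- ccp_intensity(delta, ras$theta_map, gammas[[chans[ci]]],
                                  optics$i0)
  }

  sharp <- vector("list", nz)  # per-plane list of ring layers
  for (d in scene$defects) {
    if (!d$kind %in% c("vesicle", "transverse_axon")) next
    planes <- d$z_center + seq_len(d$span) - 1L
    layer <- array(0, c(h, w, 3))
    for (ci in 1:3)
      layer[, , ci] <- ring_intensity(d, scene, optics, gammas, chans[ci])
    for (z in planes)
      sharp[[z + 1L]] <- if (is.null(sharp[[z + 1L]])) layer else
        pmax(sharp[[z + 1L]], layer)
  }

  vox <- array(0, c(nz, h, w, 3))
  for (z in 0:(nz - 1)) {
    sig <- scene$defocus_sigma_per_um * abs(z - scene$z_focus) * scene$z_step_um
    for (ci in 1:3) {
      pl <- if (sig > 0.05) EBImage::gblur(base[, , ci], sigma = sig) else
        base[, , ci]
      if (!is.null(sharp[[z + 1L]])) pl <- pmax(pl, sharp[[z + 1L]][, , ci])
      vox[z + 1L, , , ci] <- pl
    }
  }
  vox <- pmin(pmax(vox, 0), optics$i0)

  if (scene$noise$gaussian_sigma > 0 || scene$noise$poisson_scale > 0) {
    vox <- with_seed(scene$seed, {
      v <- vox
      if (scene$noise$poisson_scale > 0) {
        sc <- scene$noise$poisson_scale
        v[] <- stats::rpois(length(v), v / optics$i0 * sc) / sc * optics$i0
      }
      if (scene$noise$gaussian_sigma > 0)
        v <- v + stats::rnorm(length(v), 0,
                              scene$noise$gaussian_sigma * optics$i0)
      v
    })
    vox <- pmax(vox, 0)
  }
  zstack(vox, pixel_size_um = scene$pixel_size_um,
         z_step_um = scene$z_step_um, channel_mode = "rgb")
}

## ---- phantom generation ----------------------------------------------------

#' Generate a random fiber-rich phantom with planted objects
#'
#' Places random fibers, fiber defects (break / swelling / blebbing cycled),
#' vesicles and transverse-axon confounders with a minimum center separation,
#' and returns the scene together with exact ground truth. Transverse axons
#' are listed as confounders, not ground truth.
#'
#' @param n_defects,n_vesicles,n_transverse Requested object counts (>= 0).
#' @param n_fibers Number of fibers.
#' @param shape `c(n_z, height, width)` of the stack.
#' @param seed Integer seed; placements are reproducible and the seed also
#'   controls rendering noise.
#' @param defect_extent,vesicle_extent Object diameters in pixels.
#' @param min_sep Minimum center-to-center separation in pixels.
#' @param axon_span Planes spanned by each transverse axon (>= 3).
#' @param margin Border (px) kept free of object centers.
#' @param noise,defocus_sigma_per_um Passed to [phantom_scene()].
#' @param stack_id Identifier used in the returned annotation frames.
#' @param max_tries Placement retries per object before a capacity error.
#' @return List with `scene` ([phantom_scene()]), `ground_truth` and
#'   `confounders` (annotation data frames).
#' @export
generate_phantom <- function(n_defects = 5, n_vesicles = 3, n_transverse = 0,
                             n_fibers = 12, shape = c(5L, 256L, 256L),
                             seed = 1L, defect_extent = 10,
                             vesicle_extent = 8, min_sep = 25,
                             axon_span = 3, margin = 16,
                             noise = list(gaussian_sigma = 0.02,
                                          poisson_scale = 0),
                             defocus_sigma_per_um = 0.6,
                             stack_id = "phantom", max_tries = 200) {
  stopifnot(n_defects >= 0, n_vesicles >= 0, n_transverse >= 0)
  shape <- as.integer(shape)
  if (n_transverse > 0 && shape[1] < axon_span)
    stop("stack too shallow for transverse axons")
  with_seed(seed, {
    h <- shape[2]; w <- shape[3]
    z_focus <- (shape[1] - 1L) %/% 2L
    fibers <- list()
    for (i in seq_len(n_fibers)) {
      ang <- stats::runif(1, 0, pi)
      cx <- stats::runif(1, 0.2 * w, 0.8 * w)
      cy <- stats::runif(1, 0.2 * h, 0.8 * h)
      half <- sqrt(h^2 + w^2)
      p1 <- c(cx - half * cos(ang), cy - half * sin(ang))
      p2 <- c(cx + half * cos(ang), cy + half * sin(ang))
      mid <- (p1 + p2) / 2 + stats::rnorm(2, 0, 6)
      path <- clip_path(rbind(p1, mid, p2), w, h)
      if (is.null(path)) next
      fibers[[length(fibers) + 1]] <-
        fiber_segment(path, thickness_d = stats::runif(1, 0.8, 1.4))
    }
    centers <- matrix(numeric(0), 0, 2)
    place <- function(extent) {
      for (t in seq_len(max_tries)) {
        c_ <- c(stats::runif(1, margin, w - margin),
                stats::runif(1, margin, h - margin))
        if (nrow(centers) == 0 ||
            min(sqrt(rowSums(sweep(centers, 2, c_)^2))) >= min_sep) {
          centers <<- rbind(centers, c_)
          return(c_)
        }
      }
      stop(structure(class = c("ccpbrm_capacity_error", "error", "condition"),
                     list(message = "could not place object without overlap",
                          call = sys.call(-1))))
    }
    defects <- list()
    kinds <- c("break", "swelling", "blebbing")
    for (i in seq_len(n_defects)) {
      c_ <- place(defect_extent)
      # anchor fiber defects on a fiber path when one is nearby enough
      defects[[length(defects) + 1]] <-
        defect_spec(kinds[(i - 1) %% 3 + 1], snap_to_fiber(c_, fibers),
                    z_focus, extent = defect_extent,
                    magnitude = stats::runif(1, 1.8, 2.5))
    }
    for (i in seq_len(n_vesicles)) {
      c_ <- place(vesicle_extent)
      defects[[length(defects) + 1]] <-
        defect_spec("vesicle", c_, sample.int(shape[1], 1) - 1L,
                    extent = vesicle_extent, magnitude = 1.5)
    }
    for (i in seq_len(n_transverse)) {
      c_ <- place(vesicle_extent)
      z0 <- sample.int(shape[1] - axon_span + 1L, 1) - 1L
      defects[[length(defects) + 1]] <-
        defect_spec("transverse_axon", c_, z0, extent = vesicle_extent,
                    magnitude = 1.5, span = axon_span)
    }
    scene <- phantom_scene(fibers, defects, shape = shape,
                           z_focus = z_focus, noise = noise,
                           defocus_sigma_per_um = defocus_sigma_per_um,
                           seed = seed)
    gt <- scene_ground_truth(scene, stack_id = stack_id)
    c(list(scene = scene), gt)
  })
}

# Move a candidate center onto the nearest fiber centerline when within
# reach, so that break/swelling defects actually sit on a fiber.
snap_to_fiber <- function(center, fibers, reach = 40) {
  best <- NULL; bestd <- reach
  for (f in fibers) {
    p <- f$path
    for (i in seq_len(nrow(p) - 1)) {
      a <- p[i, ]; v <- p[i + 1, ] - a; len2 <- sum(v^2)
      if (len2 == 0) next
      t_ <- min(1, max(0, sum((center - a) * v) / len2))
      q <- a + t_ * v
      d <- sqrt(sum((center - q)^2))
      if (d < bestd) { bestd <- d; best <- q }
    }
  }
  if (is.null(best)) center else best
}

# Clip a polyline to the image rectangle; returns NULL if fully outside.
clip_path <- function(path, w, h) {
  keep <- path
  keep[, 1] <- pmin(pmax(keep[, 1], 1), w - 2)
  keep[, 2] <- pmin(pmax(keep[, 2], 1), h - 2)
  if (all(duplicated(keep)[-1])) return(NULL)
  keep
}

# Evaluate expr with a local RNG state seeded by `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
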