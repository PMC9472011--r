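# Deterministic synthetic-fixture generators.
#
# Every module is exercised against fixtures whose ground truth is known by
# construction: a dot-grid recognition target rendered through both cameras
# of a stereo rig, stereo renders of a coloured wound on textured skin,
# crater point clouds with closed-form rim/volume truth, and hand-eye pose
# sets built from a known camera-to-end-effector transform. Same parameters
# + seed give byte-identical output.

#' Build a parallel-axis stereo rig
#'
#' Left and right cameras share orientation and are separated by `baseline`
#' along the camera x axis; `pose` places the rig midpoint in the world.
#'
#' @param baseline Distance between optical centres, mm.
#' @param fx,fy Focal lengths, px.
#' @param width,height Image size, px.
#' @param pose Rig midpoint pose (camera frame: z = viewing direction).
#' @return A [stereo_rig()]; image size rides along as attributes.
#' @export
make_stereo_rig <- function(baseline = 60, fx = 1200, fy = 1200,
                            width = 640, height = 480,
                            pose = rt_identity()) {
  half <- baseline / 2
  off <- function(dx) rt_compose(pose, rigid_transform(diag(3), c(dx, 0, 0)))
  rig <- stereo_rig(
    camera_model(fx, fy, x0 = (width - 1) / 2, y0 = (height - 1) / 2,
                 s = 0, pose = off(-half)),
    camera_model(fx, fy, x0 = (width - 1) / 2, y0 = (height - 1) / 2,
                 s = 0, pose = off(half)))
  attr(rig, "width") <- as.integer(width)
  attr(rig, "height") <- as.integer(height)
  rig
}

#' Rig pose observing the world origin from distance and depression angle
#'
#' Places the rig midpoint at `distance` from the world origin, optical
#' axis hitting the origin at the given depression angle (angle below the
#' horizontal; pi/2 = top-down).
#'
#' @param distance Camera-to-target distance, mm.
#' @param depression Depression angle, rad, in (0, pi/2].
#' @return A `rigid_transform` usable as `pose` in [make_stereo_rig()].
#' @export
observe_pose <- function(distance, depression) {
  stopifnot(distance > 0, depression > 0, depression <= pi / 2)
  d <- c(0, cos(depression), -sin(depression))  # viewing direction
  C <- -d * distance
  x <- c(1, 0, 0)
  y <- c(d[2] * x[3] - d[3] * x[2],
         d[3] * x[1] - d[1] * x[3],
         d[1] * x[2] - d[2] * x[1])
  y <- y / sqrt(sum(y^2))
  rigid_transform(cbind(x, y, d), C, tol = 1e-9)
}

# rasterize anti-aliased discs into an image; img is [row, col, 3] in [0,1].
# edge_px is the width of the linear intensity ramp at the disc boundary
# (slight defocus; keeps sub-pixel centroids accurate after detection).
render_discs <- function(img, cam, centers, radius_mm, color, edge_px = 2) {
  h <- dim(img)[1]; w <- dim(img)[2]
  ext <- rt_inverse(cam$pose)
  for (i in seq_len(nrow(centers))) {
    X <- centers[i, ]
    Xc <- rt_apply(ext, X)
    if (Xc[3] <= 0) next
    uv <- project(cam, X)
    r_px <- cam$fx * radius_mm / Xc[3]
    pad <- r_px + edge_px + 1
    c0 <- max(1, floor(uv[1] + 1 - pad)); c1 <- min(w, ceiling(uv[1] + 1 + pad))
    r0 <- max(1, floor(uv[2] + 1 - pad)); r1 <- min(h, ceiling(uv[2] + 1 + pad))
    if (c0 > c1 || r0 > r1) next
    cols <- c0:c1; rows <- r0:r1
    du <- (cols - 1) - uv[1]
    dv <- (rows - 1) - uv[2]
    dist <- sqrt(outer(dv^2, du^2, "+"))
    cov <- pmin(1, pmax(0, 0.5 + (r_px - dist) / edge_px))
    for (k in 1:3) {
      img[rows, cols, k] <- img[rows, cols, k] * (1 - cov) + color[k] * cov
    }
  }
  img
}

#' Render the dot-grid recognition target through a stereo rig
#'
#' The static-recognition target: dots of 4 mm diameter arranged in a
#' 10 x 8 matrix with a pitch of 20 mm, lying in the world z = 0 plane and
#' centred on the origin, viewed from the given distance and depression
#' angle. Black dots on a white board, anti-aliased. Rendering is
#' deterministic; the truth table carries the 3D dot centres.
#'
#' @param rig A [make_stereo_rig()] rig (its `pose` is overridden by the
#'   distance/depression placement).
#' @param distance Camera-to-grid distance, mm.
#' @param depression Depression angle, rad.
#' @param ncol_grid,nrow_grid Grid size (default 10 x 8).
#' @param pitch Dot pitch, mm (default 20).
#' @param dot_diameter Dot diameter, mm (default 4).
#' @return A list: `left`, `right` (RGB arrays), `truth` (tibble `dot`,
#'   `x`, `y`, `z`), `rig` (repositioned rig), `distance`, `depression`.
#'   Errors if any dot projects outside either view.
#' @export
gen_dot_grid <- function(rig = make_stereo_rig(), distance = 500,
                         depression = pi / 3, ncol_grid = 10, nrow_grid = 8,
                         pitch = 20, dot_diameter = 4) {
  pose <- observe_pose(distance, depression)
  rig2 <- make_stereo_rig(baseline = rig$baseline, fx = rig$left$fx,
                          fy = rig$left$fy,
                          width = attr(rig, "width"),
                          height = attr(rig, "height"), pose = pose)
  w <- attr(rig2, "width"); h <- attr(rig2, "height")
  gx <- (seq_len(ncol_grid) - (ncol_grid + 1) / 2) * pitch
  gy <- (seq_len(nrow_grid) - (nrow_grid + 1) / 2) * pitch
  centers <- as.matrix(expand.grid(x = gx, y = gy))
  centers <- cbind(centers, z = 0)
  for (cam in list(rig2$left, rig2$right)) {
    uv <- project(cam, centers)
    if (any(uv[, 1] < 2 | uv[, 1] > w - 3 | uv[, 2] < 2 | uv[, 2] > h - 3)) {
      stop("grid out of view: reduce distance/field or depression")
    }
  }
  blank <- array(1, c(h, w, 3))
  left <- render_discs(blank, rig2$left, centers, dot_diameter / 2, c(0, 0, 0))
  right <- render_discs(blank, rig2$right, centers, dot_diameter / 2, c(0, 0, 0))
  list(left = left, right = right,
       truth = tibble::tibble(dot = seq_len(nrow(centers)),
                              x = centers[, 1], y = centers[, 2],
                              z = centers[, 3]),
       rig = rig2, distance = distance, depression = depression)
}

#' Render a synthetic wound on textured skin through a stereo rig
#'
#' A deep-red circular wound on a skin-toned background with seeded
#' per-pixel texture noise plus scattered dark/bright specks (pores and
#' specular highlights) so that each channel spans the full intensity range
#' and linear normalization is the identity on the clean render. The wound
#' hue band is well separated from the skin hue, making the default
#' [segmentation_config()] meaningful.
#'
#' @param rig A stereo rig (see [make_stereo_rig()]).
#' @param distance,depression Rig placement (see [observe_pose()]).
#' @param wound_center Wound centre in world coordinates (on z = 0).
#' @param wound_radius Wound radius, mm (0 = background-only image).
#' @param seed Texture seed.
#' @param wound_color,skin_color RGB triples.
#' @return A list: `left`, `right`, `truth` (wound centre 3D + projected
#'   centroids per view), `rig`.
#' @export
gen_stereo_wound <- function(rig = make_stereo_rig(), distance = 400,
                             depression = pi / 2.4,
                             wound_center = c(0, 0, 0), wound_radius = 6,
                             seed = 1L,
                             wound_color = c(0.65, 0.10, 0.12),
                             skin_color = c(0.80, 0.62, 0.50)) {
  pose <- observe_pose(distance, depression)
  rig2 <- make_stereo_rig(baseline = rig$baseline, fx = rig$left$fx,
                          fy = rig$left$fy,
                          width = attr(rig, "width"),
                          height = attr(rig, "height"), pose = pose)
  w <- attr(rig2, "width"); h <- attr(rig2, "height")
  mk <- function(cam, side_seed) {
    withr::with_seed(as.integer(seed) + side_seed, {
      img <- array(rep(skin_color, each = h * w), c(h, w, 3))
      img <- img + array(stats::runif(h * w * 3, -0.05, 0.05), c(h, w, 3))
      # seeded specks pinning the per-channel range (normalization identity)
      n_speck <- 40L
      sr <- sample.int(h, n_speck); sc <- sample.int(w, n_speck)
      img[cbind(sr[1:20], sc[1:20], sample(3, 20, TRUE))] <- 0
      img[cbind(sr[21:40], sc[21:40], sample(3, 20, TRUE))] <- 1
      img <- array(pmin(pmax(img, 0), 1), dim(img))
      if (wound_radius > 0) {
        img <- render_discs(img, cam, matrix(wound_center, 1, 3),
                            wound_radius, wound_color)
      }
      img
    })
  }
  left <- mk(rig2$left, 0L)
  right <- mk(rig2$right, 1L)
  truth <- list(center3d = wound_center,
                uv_left = if (wound_radius > 0) project(rig2$left, wound_center) else NULL,
                uv_right = if (wound_radius > 0) project(rig2$right, wound_center) else NULL,
                radius = wound_radius)
  list(left = left, right = right, truth = truth, rig = rig2)
}

# analytic crater depth (negative z) at planar radius rho
crater_depth <- function(kind, rho, radius, depth) {
  switch(kind,
         hemisphere = ifelse(rho < radius, -sqrt(pmax(radius^2 - rho^2, 0)), 0),
         ellipsoid = ifelse(rho < radius,
                            -depth * sqrt(pmax(1 - (rho / radius)^2, 0)), 0),
         punch_cylinder = ifelse(rho < radius, -depth, 0),
         stop("unknown crater kind: ", kind))
}

#' Generate a crater point cloud with closed-form truth
#'
#' A flat skin plate (z = 0) with a depressed defect centred at the origin:
#' `hemisphere` (depth = radius), `ellipsoid` (half-ellipsoid of given
#' depth) or `punch_cylinder` (flat-bottomed biopsy punch). Points are
#' sampled on a regular grid at `sample_step` with optional Gaussian height
#' noise. Truth: rim circle of the given radius and closed-form volume
#' (2/3 pi r^3, 2/3 pi r^2 d, pi r^2 d respectively).
#'
#' @param kind `"hemisphere"`, `"ellipsoid"` or `"punch_cylinder"`.
#' @param radius Crater radius, mm (> 0).
#' @param depth Crater depth, mm (hemisphere ignores it and uses `radius`).
#' @param sample_step Cloud sampling pitch, mm.
#' @param margin Plate margin beyond the rim, mm.
#' @param noise_sd Height noise, mm.
#' @param seed Noise seed.
#' @return A list: `cloud` (n x 3), `truth` (list with `volume_mm3`,
#'   `rim_radius`, `kind`, `depth`).
#' @export
gen_crater_cloud <- function(kind = "hemisphere", radius = 5, depth = radius,
                             sample_step = 0.125, margin = 3,
                             noise_sd = 0, seed = 1L) {
  stopifnot(radius > 0, depth > 0, sample_step > 0, margin > 0)
  if (kind == "hemisphere") depth <- radius
  ext <- radius + margin
  xs <- seq(-ext, ext, by = sample_step)
  g <- as.matrix(expand.grid(x = xs, y = xs))
  rho <- sqrt(g[, 1]^2 + g[, 2]^2)
  z <- crater_depth(kind, rho, radius, depth)
  if (noise_sd > 0) {
    z <- z + withr::with_seed(as.integer(seed),
                              stats::rnorm(length(z), 0, noise_sd))
  }
  vol <- switch(kind,
                hemisphere = 2 * pi * radius^3 / 3,
                ellipsoid = 2 * pi * radius^2 * depth / 3,
                punch_cylinder = pi * radius^2 * depth)
  list(cloud = cbind(g, z = z),
       truth = list(volume_mm3 = vol, rim_radius = radius, kind = kind,
                    depth = depth))
}

#' Analytic crater mesh (exact node heights)
#'
#' Builds the crater surface of [gen_crater_cloud()] directly as a
#' height-field mesh whose node heights are exact analytic values — no
#' reconstruction smoothing. Useful when rim/cap behaviour must be checked
#' without reconstruction error.
#'
#' @inheritParams gen_crater_cloud
#' @param grid_step Mesh grid pitch, mm.
#' @return A list: `mesh` (`surface_mesh` with grid metadata), `truth` as in
#'   [gen_crater_cloud()].
#' @export
gen_crater_mesh <- function(kind = "hemisphere", radius = 5, depth = radius,
                            grid_step = 0.25, margin = 3) {
  stopifnot(radius > 0, depth > 0, grid_step > 0, margin > 0)
  if (kind == "hemisphere") depth <- radius
  ext <- radius + margin
  xs <- seq(-ext, ext, by = grid_step)
  Z <- matrix(NA_real_, length(xs), length(xs))
  for (j in seq_along(xs)) {
    rho <- sqrt(xs^2 + xs[j]^2)
    Z[, j] <- crater_depth(kind, rho, radius, depth)
  }
  vol <- switch(kind,
                hemisphere = 2 * pi * radius^3 / 3,
                ellipsoid = 2 * pi * radius^2 * depth / 3,
                punch_cylinder = pi * radius^2 * depth)
  list(mesh = build_grid_mesh(xs, xs, Z),
       truth = list(volume_mm3 = vol, rim_radius = radius, kind = kind,
                    depth = depth))
}

#' Spherical-cap test mesh with exact radial normals
#'
#' The upper cap of a sphere of the given radius centred at the origin,
#' triangulated on a regular grid over the footprint `rho <= fraction *
#' radius`. Vertices lie exactly on the sphere and vertex normals are the
#' exact radial directions, so conformal-projection accuracy can be checked
#' against the analytic surface.
#'
#' @param radius Sphere radius, mm.
#' @param grid_step Grid pitch, mm.
#' @param fraction Footprint radius as a fraction of the sphere radius.
#' @return A `surface_mesh` with height-field metadata.
#' @export
gen_sphere_cap <- function(radius = 20, grid_step = 0.5, fraction = 0.7) {
  stopifnot(radius > 0, grid_step > 0, fraction > 0, fraction < 1)
  ext <- radius * fraction
  xs <- seq(-ext, ext, by = grid_step)
  Z <- matrix(NA_real_, length(xs), length(xs))
  for (j in seq_along(xs)) {
    rho2 <- xs^2 + xs[j]^2
    ok <- rho2 <= ext^2
    Z[ok, j] <- sqrt(radius^2 - rho2[ok])
  }
  mesh <- build_grid_mesh(xs, xs, Z)
  mesh$normals <- mesh$vertices / radius
  mesh
}

#' Generate a hand-eye calibration sample set from known transforms
#'
#' Draws `n` end-effector poses with guaranteed rotation-axis diversity,
#' back-computes each camera-in-grid pose from the eye-in-hand identity,
#' then perturbs it with Gaussian rotation/translation noise. With zero
#' noise the set satisfies the identity exactly.
#'
#' @param H_ce True camera-in-end-effector transform.
#' @param H_gw True grid-in-base transform.
#' @param n Number of poses (>= 3).
#' @param noise_rot_sd Rotation noise, rad.
#' @param noise_trans_sd Translation noise, mm.
#' @param seed RNG seed.
#' @return A list of [handeye_sample()] objects.
#' @export
gen_handeye_set <- function(H_ce, H_gw, n = 10, noise_rot_sd = 0,
                            noise_trans_sd = 0, seed = 1L) {
  stopifnot(inherits(H_ce, "rigid_transform"), inherits(H_gw, "rigid_transform"),
            n >= 3)
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(n), function(i) {
      # deterministic base axes spanning the sphere + random wobble
      ax <- switch((i - 1) %% 3 + 1,
                   c(1, 0.2, 0), c(0, 1, 0.2), c(0.2, 0, 1))
      ax <- ax + stats::rnorm(3, 0, 0.2)
      ax <- ax / sqrt(sum(ax^2))
      ang <- stats::runif(1, 0.3, 1.2)
      Rw <- axis_angle_rotation(ax, ang)
      pw <- stats::runif(3, -200, 200)
      H_ew <- rigid_transform(Rw, pw)
      H_cg <- rt_compose(rt_inverse(H_gw), rt_compose(H_ew, H_ce))
      if (noise_rot_sd > 0 || noise_trans_sd > 0) {
        dR <- axis_angle_rotation(stats::rnorm(3), stats::rnorm(1, 0, noise_rot_sd))
        dp <- stats::rnorm(3, 0, noise_trans_sd)
        H_cg <- rt_compose(H_cg, rigid_transform(dR, dp, tol = 1e-6))
      }
      handeye_sample(H_ew, H_cg)
    })
  })
}

# rotation about (unnormalized) axis by angle
axis_angle_rotation <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) return(diag(3))
  a <- axis / n
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

#' Read/write RGB images as PNG
#'
#' @param img Numeric array `[row, col, 3]` in `[0, 1]`.
#' @param path File path.
#' @export
write_image_png <- function(img, path) {
  png::writePNG(img, path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3]
  img
}
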