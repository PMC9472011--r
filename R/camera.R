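# Pinhole camera model, binocular triangulation and the recognition-error
# metrics used to evaluate static wound localization.

#' Pinhole camera model
#'
#' Linear pinhole model: a point `X` (world frame, mm) projects to pixel
#' coordinates through `Z * (u, v, 1)' = K [R | t] (X, 1)'`, where
#' `K = [[fx, s, x0], [0, fy, y0], [0, 0, 1]]` is the intrinsic matrix and
#' the extrinsic `[R | t]` maps world to camera coordinates. `pose` stores
#' the camera pose *in* the world frame (camera-to-world); the extrinsic is
#' its inverse. Pixel convention: (u, v) = (column, row), origin at the
#' top-left pixel centre, 0-based.
#'
#' @param fx,fy Focal lengths (px), > 0.
#' @param x0,y0 Principal point (px).
#' @param s Skew (px), default 0.
#' @param pose A `rigid_transform`: camera frame expressed in the world frame.
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(fx, fy, x0, y0, s = 0, pose = rt_identity()) {
  stopifnot(fx > 0, fy > 0, is.finite(x0), is.finite(y0), is.finite(s),
            inherits(pose, "rigid_transform"))
  structure(list(fx = fx, fy = fy, x0 = x0, y0 = y0, s = s, pose = pose),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("<camera_model> fx=%.1f fy=%.1f x0=%.1f y0=%.1f s=%.2f px\n",
              x$fx, x$fy, x$x0, x$y0, x$s))
  invisible(x)
}

#' Intrinsic matrix K of a camera
#' @param cam A `camera_model`.
#' @return The 3x3 intrinsic matrix.
#' @export
camera_K <- function(cam) {
  matrix(c(cam$fx, 0, 0, cam$s, cam$fy, 0, cam$x0, cam$y0, 1), 3, 3)
}

# 3x4 projection matrix K [R|t] (world -> pixels)
camera_P <- function(cam) {
  ext <- rt_inverse(cam$pose)
  camera_K(cam) %*% cbind(ext$R, ext$p)
}

#' Binocular stereo rig
#'
#' @param left,right `camera_model` objects with distinct optical centres.
#' @return An object of class `stereo_rig`; `baseline` (mm) is the distance
#'   between the two optical centres.
#' @export
stereo_rig <- function(left, right) {
  stopifnot(inherits(left, "camera_model"), inherits(right, "camera_model"))
  baseline <- sqrt(sum((left$pose$p - right$pose$p)^2))
  if (baseline <= 0) stop("degenerate rig: coincident optical centers")
  structure(list(left = left, right = right, baseline = baseline),
            class = "stereo_rig")
}

#' @export
print.stereo_rig <- function(x, ...) {
  cat(sprintf("<stereo_rig> baseline = %.2f mm\n", x$baseline))
  invisible(x)
}

#' Project world points through a camera
#'
#' @param cam A `camera_model`.
#' @param X A length-3 point or n x 3 matrix of world points (mm).
#' @return For a single point, `c(u, v)`; for a matrix, an n x 2 matrix.
#'   Points with nonpositive camera depth raise a behind-camera error.
#' @export
project <- function(cam, X) {
  stopifnot(inherits(cam, "camera_model"))
  one <- !is.matrix(X)
  if (one) X <- matrix(X, 1, 3)
  stopifnot(ncol(X) == 3)
  ext <- rt_inverse(cam$pose)
  Xc <- rt_apply(ext, X)
  if (any(Xc[, 3] <= 0)) stop("behind-camera: point has nonpositive depth")
  u <- (cam$fx * Xc[, 1] + cam$s * Xc[, 2]) / Xc[, 3] + cam$x0
  v <- cam$fy * Xc[, 2] / Xc[, 3] + cam$y0
  uv <- cbind(u = u, v = v)
  if (one) uv[1, ] else uv
}

#' Triangulate a 3D point from a stereo pixel pair
#'
#' Simultaneous solution of the two projection equations: the four stacked
#' linear constraints (homogeneous DLT, projective scale eliminated) are
#' solved by SVD. The linear solve is the production path; nonlinear
#' reprojection refinement exists separately as an independent cross-check.
#'
#' @param rig A `stereo_rig`.
#' @param uv_left,uv_right Pixel coordinates `c(u, v)` in each camera.
#' @return A list with `point` (length-3, mm), `reprojection_residual_px`
#'   (RMS over the four pixel residuals). Parallel rays raise a
#'   degenerate-geometry error.
#' @export
triangulate <- function(rig, uv_left, uv_right) {
  stopifnot(inherits(rig, "stereo_rig"), length(uv_left) == 2, length(uv_right) == 2)
  r1 <- pixel_ray(rig$left, uv_left)
  r2 <- pixel_ray(rig$right, uv_right)
  cr <- c(r1[2] * r2[3] - r1[3] * r2[2],
          r1[3] * r2[1] - r1[1] * r2[3],
          r1[1] * r2[2] - r1[2] * r2[1])
  if (sqrt(sum(cr^2)) < 1e-12) {
    stop("degenerate geometry: parallel pixel rays, point at infinity")
  }
  P1 <- camera_P(rig$left)
  P2 <- camera_P(rig$right)
  A <- rbind(uv_left[1] * P1[3, ] - P1[1, ],
             uv_left[2] * P1[3, ] - P1[2, ],
             uv_right[1] * P2[3, ] - P2[1, ],
             uv_right[2] * P2[3, ] - P2[2, ])
  sv <- svd(A, nu = 0, nv = 4)
  Xh <- sv$v[, 4]
  if (abs(Xh[4]) < 1e-14) stop("degenerate geometry: point at infinity")
  X <- Xh[1:3] / Xh[4]
  res <- sqrt(mean(c(project(rig$left, X) - uv_left,
                     project(rig$right, X) - uv_right)^2))
  list(point = X, reprojection_residual_px = res)
}

# unit viewing ray of a pixel, in world frame
pixel_ray <- function(cam, uv) {
  Kinv <- solve(camera_K(cam))
  d <- as.numeric(Kinv %*% c(uv, 1))
  d <- as.numeric(cam$pose$R %*% d)
  d / sqrt(sum(d^2))
}

#' Nonlinear (reprojection-minimizing) triangulation
#'
#' Independent oracle for [triangulate()]: minimizes the sum of squared
#' pixel reprojection errors over the 3D point with `stats::optim` (BFGS),
#' started from the linear solution.
#'
#' @inheritParams triangulate
#' @return As [triangulate()].
#' @export
triangulate_nonlinear <- function(rig, uv_left, uv_right) {
  x0 <- triangulate(rig, uv_left, uv_right)$point
  f <- function(X) {
    el <- try(project(rig$left, X) - uv_left, silent = TRUE)
    er <- try(project(rig$right, X) - uv_right, silent = TRUE)
    if (inherits(el, "try-error") || inherits(er, "try-error")) return(1e12)
    sum(el^2) + sum(er^2)
  }
  opt <- stats::optim(x0, f, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 500))
  X <- opt$par
  res <- sqrt(mean(c(project(rig$left, X) - uv_left,
                     project(rig$right, X) - uv_right)^2))
  list(point = X, reprojection_residual_px = res)
}

#' Recognition-error metrics for static target localization
#'
#' Overall localization accuracy of the binocular system is summarized by the
#' relative range error and the angular deviation:
#' \deqn{E_d = |l - l_0| / l_0, \qquad E_a = \arctan(dP \sin\theta / l_0),}
#' where `l` is the calculated camera-object distance, `l0` the real
#' distance, `dP` the planar recognition error of the target, and `theta`
#' the depression angle of the camera. These metrics remove the influence of
#' the camera's internal parameters from the raw recognition error.
#'
#' @param l Calculated camera-object distance(s), mm.
#' @param l0 Real distance(s), mm, > 0.
#' @param dP Planar recognition error(s), mm.
#' @param theta Depression angle, radians, in `[0, pi/2]`.
#' @return A tibble with columns `l`, `l0`, `dP`, `theta`, `Ed`
#'   (dimensionless) and `Ea` (radians).
#' @examples
#' recognition_errors(l = 504, l0 = 500, dP = 0.8, theta = pi / 6)
#' @export
recognition_errors <- function(l, l0, dP, theta) {
  if (any(l0 <= 0)) stop("l0 must be > 0")
  stopifnot(all(theta >= 0), all(theta <= pi / 2 + 1e-12))
  tibble::tibble(
    l = l, l0 = l0, dP = dP, theta = theta,
    Ed = abs(l - l0) / l0,
    Ea = atan(dP * sin(theta) / l0)
  )
}
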