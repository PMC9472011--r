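# Rigid-body math shared by every module.
# Conventions (fixed package-wide): millimetres and radians internally;
# right-handed frames; Euler angles are intrinsic Z-Y-X (yaw, pitch, roll);
# tool approach axis is tool +z, printing poses set tool +z anti-parallel to
# the local surface normal.

#' Rigid transform (rotation + translation)
#'
#' A proper rigid transform in SE(3): a 3x3 rotation matrix `R` (orthonormal,
#' det +1) and a translation vector `p` in millimetres. This is the currency
#' of every module: camera extrinsics, end-effector poses, hand-eye unknowns
#' and Denavit-Hartenberg link transforms are all `rigid_transform` objects.
#'
#' @param R 3x3 rotation matrix.
#' @param p length-3 translation vector (mm). Default zero.
#' @param tol orthonormality tolerance (default 1e-9).
#' @return An object of class `rigid_transform` with fields `R` and `p`.
#' @examples
#' rt <- rigid_transform(diag(3), c(1, 2, 3))
#' rt_compose(rt, rt_inverse(rt))  # identity
#' @export
rigid_transform <- function(R = diag(3), p = c(0, 0, 0), tol = 1e-9) {
  R <- matrix(as.numeric(R), 3, 3)
  p <- as.numeric(p)
  stopifnot(length(p) == 3, all(is.finite(R)), all(is.finite(p)))
  err_orth <- max(abs(crossprod(R) - diag(3)))
  if (err_orth > tol || abs(det(R) - 1) > tol) {
    stop("R is not a proper rotation (orthonormality/det error ",
         format(max(err_orth, abs(det(R) - 1))), " > ", format(tol), ")")
  }
  structure(list(R = R, p = p), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n")
  m <- cbind(x$R, x$p)
  dimnames(m) <- list(c("x", "y", "z"), c("R.1", "R.2", "R.3", "p[mm]"))
  print(round(m, 6))
  invisible(x)
}

#' Identity transform
#' @return The identity `rigid_transform`.
#' @export
rt_identity <- function() rigid_transform(diag(3), c(0, 0, 0))

#' Compose two rigid transforms
#'
#' `rt_compose(a, b)` maps a point first through `b`, then through `a`,
#' i.e. the matrix product of the homogeneous forms.
#'
#' @param a,b `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
rt_compose <- function(a, b) {
  stopifnot(inherits(a, "rigid_transform"), inherits(b, "rigid_transform"))
  structure(list(R = a$R %*% b$R, p = as.numeric(a$R %*% b$p) + a$p),
            class = "rigid_transform")
}

#' Invert a rigid transform
#' @param a A `rigid_transform`.
#' @return The inverse transform.
#' @export
rt_inverse <- function(a) {
  stopifnot(inherits(a, "rigid_transform"))
  Rt <- t(a$R)
  structure(list(R = Rt, p = as.numeric(-Rt %*% a$p)), class = "rigid_transform")
}

#' Convert to / from the 4x4 homogeneous matrix form
#' @param a A `rigid_transform`.
#' @return `rt_as_matrix`: a 4x4 matrix with last row (0,0,0,1).
#' @export
rt_as_matrix <- function(a) {
  stopifnot(inherits(a, "rigid_transform"))
  rbind(cbind(a$R, a$p), c(0, 0, 0, 1))
}

#' @param m A 4x4 homogeneous matrix.
#' @param tol orthonormality tolerance.
#' @rdname rt_as_matrix
#' @export
rt_from_matrix <- function(m, tol = 1e-9) {
  stopifnot(is.matrix(m), all(dim(m) == c(4, 4)))
  if (max(abs(m[4, ] - c(0, 0, 0, 1))) > tol) stop("last row is not (0,0,0,1)")
  rigid_transform(m[1:3, 1:3], m[1:3, 4], tol = tol)
}

#' Apply a rigid transform to points
#' @param a A `rigid_transform`.
#' @param x A length-3 vector or an n x 3 matrix of points (mm).
#' @return Transformed points, same shape as `x`.
#' @export
rt_apply <- function(a, x) {
  stopifnot(inherits(a, "rigid_transform"))
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 3)
    sweep(x %*% t(a$R), 2, a$p, "+")
  } else {
    stopifnot(length(x) == 3)
    as.numeric(a$R %*% x) + a$p
  }
}

#' Geodesic distance between two rotations
#'
#' Uses the sine form `2 asin(||R1'R2 - I||_F / (2 sqrt(2)))`, which keeps
#' full precision for small angles (the arccos-of-trace form bottoms out
#' near 2e-8 rad in double precision).
#'
#' @param R1,R2 3x3 rotation matrices.
#' @return Angle in radians of the relative rotation.
#' @export
rotation_distance <- function(R1, R2) {
  d <- sqrt(sum((crossprod(R1, R2) - diag(3))^2))
  2 * asin(pmin(1, d / (2 * sqrt(2))))
}

# --- Euler angles (intrinsic Z-Y-X) --------------------------------------

#' Euler angles to rotation matrix (intrinsic Z-Y-X)
#'
#' Waypoint orientations are carried as yaw-pitch-roll Euler angles; the
#' rotation is `Rz(yaw) %*% Ry(pitch) %*% Rx(roll)`.
#'
#' @param yaw,pitch,roll Angles in radians.
#' @return A 3x3 rotation matrix.
#' @export
euler_to_rotation <- function(yaw, pitch, roll) {
  stopifnot(is.finite(yaw), is.finite(pitch), is.finite(roll))
  cz <- cos(yaw);  sz <- sin(yaw)
  cy <- cos(pitch); sy <- sin(pitch)
  cx <- cos(roll); sx <- sin(roll)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Rotation matrix to Euler angles (intrinsic Z-Y-X)
#'
#' Inverse of [euler_to_rotation()]. Near gimbal lock (|pitch| within 1e-6 of
#' pi/2) yaw and roll are not separately observable; the returned list carries
#' `gimbal_lock = TRUE` and the conventional roll = 0 solution.
#'
#' @param R A 3x3 rotation matrix.
#' @return A list with `yaw`, `pitch`, `roll` (radians) and `gimbal_lock`.
#' @export
rotation_to_euler <- function(R) {
  stopifnot(is.matrix(R), all(dim(R) == c(3, 3)))
  sy <- -R[3, 1]
  sy <- pmin(1, pmax(-1, sy))
  pitch <- asin(sy)
  if (abs(abs(pitch) - pi / 2) < 1e-6) {
    # gimbal lock: only yaw +/- roll observable; fix roll = 0
    yaw <- atan2(-R[1, 2], R[2, 2])
    list(yaw = yaw, pitch = pitch, roll = 0, gimbal_lock = TRUE)
  } else {
    list(yaw = atan2(R[2, 1], R[1, 1]),
         pitch = pitch,
         roll = atan2(R[3, 2], R[3, 3]),
         gimbal_lock = FALSE)
  }
}

# --- Plane fitting --------------------------------------------------------

#' Total least-squares plane through 3D points
#'
#' Fits the plane `n . x = d` minimizing orthogonal distances (smallest
#' singular vector of the centred point matrix). Wound orientation capture
#' works this way: the pose of a rigidly moving wound is recovered from
#' n >= 3 identified points. The normal is signed into the +z half-space
#' (toward an observing camera looking down -z); for vertical planes the sign
#' is resolved toward +x, then +y.
#'
#' @param points An n x 3 matrix of points (mm), n >= 3, not collinear.
#' @return A list of class `plane3d`: unit `normal`, offset `d` (mm), and
#'   `rms_residual` (mm).
#' @export
fit_plane <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("degenerate geometry: need at least 3 points")
  stopifnot(ncol(points) == 3, all(is.finite(points)))
  ctr <- colMeans(points)
  X <- sweep(points, 2, ctr)
  sv <- svd(X, nu = 0, nv = 3)
  # collinear (or coincident): the two smallest singular values both ~ 0
  scale <- max(sv$d[1], 1e-12)
  if (sv$d[2] / scale < 1e-9) {
    stop("degenerate geometry: points are collinear or coincident")
  }
  n <- sv$v[, 3]
  if (n[3] < 0 || (n[3] == 0 && (n[1] < 0 || (n[1] == 0 && n[2] < 0)))) n <- -n
  structure(list(normal = n,
                 d = sum(n * ctr),
                 rms_residual = sv$d[3] / sqrt(nrow(points))),
            class = "plane3d")
}

#' @export
print.plane3d <- function(x, ...) {
  cat(sprintf("<plane3d> n = (%.6f, %.6f, %.6f), d = %.4f mm, rms = %.3g mm\n",
              x$normal[1], x$normal[2], x$normal[3], x$d, x$rms_residual))
  invisible(x)
}

# JSON serialization with explicit convention header ----------------------

#' Serialize / deserialize rigid transforms as JSON
#'
#' Transforms are stored as `{"R": 9 row-major floats, "p": 3 floats}` plus a
#' convention header (units, Euler convention) so files are self-describing.
#'
#' @param x A `rigid_transform` or a named list of them.
#' @param path Output / input file path.
#' @export
write_transforms_json <- function(x, path) {
  if (inherits(x, "rigid_transform")) x <- list(transform = x)
  stopifnot(all(vapply(x, inherits, logical(1), "rigid_transform")))
  obj <- list(
    convention = list(units = "mm", rotation = "row-major 3x3",
                      euler = "intrinsic Z-Y-X yaw-pitch-roll, radians"),
    transforms = lapply(x, function(t) list(R = as.numeric(t(t$R)), p = t$p))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transforms_json
#' @export
read_transforms_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(obj$transforms, function(t) {
    rigid_transform(matrix(as.numeric(t$R), 3, 3, byrow = TRUE), as.numeric(t$p))
  })
  out
}

# internal: random rotation via quaternion (used by fixtures and tests)
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  quat_to_rotation(q)
}

quat_to_rotation <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

rotation_to_quat <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(diag(R))
    j <- i %% 3 + 1; k <- j %% 3 + 1
    s <- sqrt(R[i, i] - R[j, j] - R[k, k] + 1) * 2
    q <- numeric(4)
    q[1] <- (R[k, j] - R[j, k]) / s
    q[i + 1] <- s / 4
    q[j + 1] <- (R[j, i] + R[i, j]) / s
    q[k + 1] <- (R[k, i] + R[i, k]) / s
  }
  q / sqrt(sum(q^2))
}

# axis-angle vector of a rotation matrix (length = angle in rad)
rotation_log <- function(R) {
  ctheta <- (sum(diag(R)) - 1) / 2
  theta <- acos(pmin(1, pmax(-1, ctheta)))
  if (theta < 1e-12) return(c(0, 0, 0))
  if (abs(pi - theta) < 1e-6) {
    # near pi: extract axis from R + I
    A <- (R + diag(3)) / 2
    ax <- sqrt(pmax(diag(A), 0))
    i <- which.max(ax)
    ax <- A[, i] / ax[i]
    ax <- ax / sqrt(sum(ax^2))
    return(ax * theta)
  }
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  v / (2 * sin(theta)) * theta
}
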