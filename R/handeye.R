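# Eye-in-hand calibration.
#
# With the camera rigidly mounted on the end-effector, every sampled robot
# pose obeys the identity
#     H_ew_i %*% H_ce  ==  H_gw %*% H_cg_i
# where H_ew_i is the end-effector pose in the manipulator base frame,
# H_cg_i the camera pose in the calibration-grid frame, H_ce the (unknown,
# constant) camera-in-end-effector transform and H_gw the (unknown,
# constant) grid-in-base transform. Eliminating the constants between
# samples i, j yields the classical AX = XB problem with
#     A_ij = inv(H_ew_j) %*% H_ew_i,   B_ij = inv(H_cg_j) %*% H_cg_i,
# solved in closed form: rotation by quaternion linear least squares over
# all informative pairs, then translation by linear least squares.

#' A single hand-eye calibration sample
#'
#' @param H_ew End-effector pose in the manipulator base frame
#'   (`rigid_transform`).
#' @param H_cg Camera pose in the calibration-grid frame (`rigid_transform`).
#' @return A list of class `handeye_sample`.
#' @export
handeye_sample <- function(H_ew, H_cg) {
  stopifnot(inherits(H_ew, "rigid_transform"), inherits(H_cg, "rigid_transform"))
  structure(list(H_ew = H_ew, H_cg = H_cg), class = "handeye_sample")
}

# quaternion left/right multiplication matrices
quat_L <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(w, x, y, z,
           -x, w, z, -y,
           -y, -z, w, x,
           -z, y, -x, w), 4, 4)
}
quat_R <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(w, x, y, z,
           -x, w, -z, y,
           -y, z, w, -x,
           -z, -y, x, w), 4, 4)
}

# axis spread (radians) of a set of rotation axes, treated as lines
axis_spread <- function(axes) {
  if (nrow(axes) < 2) return(0)
  best <- 0
  for (i in seq_len(nrow(axes) - 1)) {
    for (j in (i + 1):nrow(axes)) {
      d <- abs(sum(axes[i, ] * axes[j, ]))
      best <- max(best, acos(pmin(1, d)))
    }
  }
  best
}

#' Solve the eye-in-hand identity for the camera-to-end-effector transform
#'
#' Closed-form AX = XB solution over all informative sample pairs. Requires
#' at least 3 samples whose relative end-effector rotations span at least
#' two non-parallel axes (axis spread > `min_axis_spread`); with a single
#' rotation axis the problem is unobservable and the function refuses with
#' a degenerate-motion error reporting the measured spread.
#'
#' @param samples A list of [handeye_sample()] objects (n >= 3).
#' @param min_axis_spread Minimum rotation-axis spread, radians
#'   (default 5 degrees).
#' @return An object of class `handeye_solution`: `H_ce` (camera in
#'   end-effector frame), `H_gw` (grid in base frame), `residuals` (per-sample
#'   tibble), `axis_spread_rad`, `n_samples`.
#' @export
handeye_solve <- function(samples, min_axis_spread = 5 * pi / 180) {
  stopifnot(is.list(samples),
            all(vapply(samples, inherits, logical(1), "handeye_sample")))
  n <- length(samples)
  if (n < 3) stop("need at least 3 samples, got ", n)

  pairs <- list()
  axes <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      A <- rt_compose(rt_inverse(samples[[j]]$H_ew), samples[[i]]$H_ew)
      B <- rt_compose(rt_inverse(samples[[j]]$H_cg), samples[[i]]$H_cg)
      ang <- sqrt(sum(rotation_log(A$R)^2))
      if (ang > 1e-8) {
        pairs[[length(pairs) + 1]] <- list(A = A, B = B)
        axes <- rbind(axes, rotation_log(A$R) / ang)
      }
    }
  }
  spread <- if (is.null(axes)) 0 else axis_spread(axes)
  if (length(pairs) < 2 || spread < min_axis_spread) {
    stop(sprintf(
      "degenerate motion: rotation-axis spread %.3f deg < %.3f deg required",
      spread * 180 / pi, min_axis_spread * 180 / pi))
  }

  # rotation: stack (L(qA) - R(qB)) blocks, smallest singular vector
  M <- do.call(rbind, lapply(pairs, function(pr) {
    quat_L(rotation_to_quat(pr$A$R)) - quat_R(rotation_to_quat(pr$B$R))
  }))
  qX <- svd(M, nu = 0, nv = 4)$v[, 4]
  RX <- quat_to_rotation(qX / sqrt(sum(qX^2)))

  # translation: (R_A - I) tX = RX tB - tA, stacked
  C <- do.call(rbind, lapply(pairs, function(pr) pr$A$R - diag(3)))
  d <- do.call(c, lapply(pairs, function(pr) as.numeric(RX %*% pr$B$p) - pr$A$p))
  tX <- as.numeric(qr.solve(C, d))
  H_ce <- rigid_transform(project_SO3(RX), tX, tol = 1e-6)

  # H_gw: residual-minimizing constant over per-sample estimates, then a
  # few alternating-average polish sweeps (X -> G -> X); each sweep averages
  # the per-sample closed-form estimates, driving consistent data to
  # machine precision
  avg_rt <- function(ts) {
    Qsum <- matrix(0, 4, 4)
    q0 <- rotation_to_quat(ts[[1]]$R)
    for (g in ts) {
      q <- rotation_to_quat(g$R)
      if (sum(q * q0) < 0) q <- -q
      Qsum <- Qsum + tcrossprod(q)
    }
    qm <- eigen(Qsum, symmetric = TRUE)$vectors[, 1]
    rigid_transform(project_SO3(quat_to_rotation(qm / sqrt(sum(qm^2)))),
                    rowMeans(vapply(ts, function(g) g$p, numeric(3))),
                    tol = 1e-6)
  }
  H_gw <- NULL
  for (sweep in 1:4) {
    H_gw <- avg_rt(lapply(samples, function(s) {
      rt_compose(rt_compose(s$H_ew, H_ce), rt_inverse(s$H_cg))
    }))
    H_ce <- avg_rt(lapply(samples, function(s) {
      rt_compose(rt_inverse(s$H_ew), rt_compose(H_gw, s$H_cg))
    }))
  }

  sol <- structure(list(H_ce = H_ce, H_gw = H_gw,
                        axis_spread_rad = spread, n_samples = n),
                   class = "handeye_solution")
  sol$residuals <- handeye_residuals(samples, sol)
  sol
}

# nearest rotation matrix (polar projection)
project_SO3 <- function(R) {
  sv <- svd(R)
  U <- sv$u; V <- sv$v
  D <- diag(c(1, 1, det(U %*% t(V))))
  U %*% D %*% t(V)
}

#' Per-sample hand-eye residuals
#'
#' For each sample compares `H_ew_i %*% H_ce` against `H_gw %*% H_cg_i`:
#' geodesic rotation distance (rad) and Euclidean translation distance (mm).
#'
#' @param samples A list of [handeye_sample()] objects.
#' @param solution A `handeye_solution`.
#' @return A tibble with columns `sample`, `rotation_rad`, `translation_mm`.
#' @export
handeye_residuals <- function(samples, solution) {
  stopifnot(inherits(solution, "handeye_solution"))
  rows <- purrr::map_dfr(seq_along(samples), function(i) {
    lhs <- rt_compose(samples[[i]]$H_ew, solution$H_ce)
    rhs <- rt_compose(solution$H_gw, samples[[i]]$H_cg)
    tibble::tibble(sample = i,
                   rotation_rad = rotation_distance(lhs$R, rhs$R),
                   translation_mm = sqrt(sum((lhs$p - rhs$p)^2)))
  })
  rows
}

#' @export
print.handeye_solution <- function(x, ...) {
  cat(sprintf(
    "<handeye_solution> %d samples, axis spread %.1f deg\n",
    x$n_samples, x$axis_spread_rad * 180 / pi))
  cat(sprintf("  residuals: max rotation %.3g rad, max translation %.3g mm\n",
              max(x$residuals$rotation_rad), max(x$residuals$translation_mm)))
  invisible(x)
}

#' Broom-style accessors for hand-eye solutions
#'
#' `tidy()` returns the per-sample residual table; `glance()` a one-row
#' summary of the fit.
#'
#' @param x A `handeye_solution`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.handeye_solution <- function(x, ...) x$residuals

#' @rdname tidy.handeye_solution
#' @export
glance.handeye_solution <- function(x, ...) {
  tibble::tibble(
    n_samples = x$n_samples,
    axis_spread_deg = x$axis_spread_rad * 180 / pi,
    max_rotation_residual_rad = max(x$residuals$rotation_rad),
    max_translation_residual_mm = max(x$residuals$translation_mm),
    rms_translation_residual_mm = sqrt(mean(x$residuals$translation_mm^2))
  )
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")
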