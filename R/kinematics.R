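# Denavit-Hartenberg kinematics of the serial bioprinting manipulator.
#
# Standard (distal) D-H convention. Each link i carries four parameters
# (link length a, twist alpha, offset d, joint-angle offset theta0) and
# joint limits; the link transform at joint angle theta is
#
#   T_i = | cos t  -sin t cos a   sin t sin a   a cos t |
#         | sin t   cos t cos a  -cos t sin a   a sin t |
#         |   0        sin a         cos a         d    |
#         |   0          0             0            1   |
#
# with t = theta0 + theta, and the end-effector pose is the ordered product
# T_1 ... T_n left-multiplied by the base pose.

#' A Denavit-Hartenberg link
#'
#' @param a Link length (mm).
#' @param alpha Link twist (rad).
#' @param d Link offset (mm).
#' @param theta0 Joint-angle offset (rad), added to the commanded angle.
#' @param limits Joint limits `c(min, max)` (rad), min < max.
#' @return A list of class `dh_link`.
#' @export
dh_link <- function(a = 0, alpha = 0, d = 0, theta0 = 0,
                    limits = c(-pi, pi)) {
  stopifnot(is.finite(a), is.finite(alpha), is.finite(d), is.finite(theta0),
            length(limits) == 2, limits[1] < limits[2])
  structure(list(a = a, alpha = alpha, d = d, theta0 = theta0,
                 limits = as.numeric(limits)),
            class = "dh_link")
}

#' A serial kinematic chain
#'
#' The shipped bioprinting arm has six revolute joints
#' (see [default_chain()]); shorter chains (planar 2R test arms, single
#' rotary links) are accepted so sub-mechanisms can be analyzed with the
#' same code.
#'
#' @param links A list of [dh_link()] objects (>= 1).
#' @param base Base pose of the chain in the world frame.
#' @return A list of class `dh_chain`.
#' @export
dh_chain <- function(links, base = rt_identity()) {
  stopifnot(is.list(links), length(links) >= 1,
            all(vapply(links, inherits, logical(1), "dh_link")),
            inherits(base, "rigid_transform"))
  structure(list(links = links, base = base), class = "dh_chain")
}

#' @export
print.dh_chain <- function(x, ...) {
  cat(sprintf("<dh_chain> %d links\n", length(x$links)))
  tab <- do.call(rbind, lapply(x$links, function(l) {
    c(a = l$a, alpha = l$alpha, d = l$d, theta0 = l$theta0,
      qmin = l$limits[1], qmax = l$limits[2])
  }))
  print(round(tab, 4))
  invisible(x)
}

#' Homogeneous transform of one D-H link
#'
#' @param link A [dh_link()].
#' @param theta Commanded joint angle (rad); the effective angle is
#'   `link$theta0 + theta`.
#' @return A `rigid_transform`.
#' @export
dh_transform <- function(link, theta) {
  stopifnot(inherits(link, "dh_link"), is.finite(theta))
  th <- link$theta0 + theta
  ct <- cos(th); st <- sin(th)
  ca <- cos(link$alpha); sa <- sin(link$alpha)
  R <- matrix(c(ct, st, 0,
                -st * ca, ct * ca, sa,
                st * sa, -ct * sa, ca), 3, 3)
  structure(list(R = R, p = c(link$a * ct, link$a * st, link$d)),
            class = "rigid_transform")
}

#' Forward kinematics
#'
#' End-effector pose: base pose times the ordered product of the link
#' transforms.
#'
#' @param chain A [dh_chain()].
#' @param q Joint angles (rad), one per link.
#' @return A `rigid_transform` (end-effector in world frame).
#' @export
forward_kinematics <- function(chain, q) {
  stopifnot(inherits(chain, "dh_chain"), length(q) == length(chain$links),
            all(is.finite(q)))
  T <- chain$base
  for (i in seq_along(chain$links)) {
    T <- rt_compose(T, dh_transform(chain$links[[i]], q[i]))
  }
  T
}

# Vectorized FK positions for an n x k matrix of joint samples (row = sample).
# Carries per-sample rotation (9 columns) and position (3 columns) through the
# chain with elementwise updates; used by the Monte Carlo workspace and the
# kinematic error map where millions of FK evaluations are needed.
fk_positions_batch <- function(chain, Q) {
  stopifnot(is.matrix(Q), ncol(Q) == length(chain$links))
  n <- nrow(Q)
  Rb <- chain$base$R; pb <- chain$base$p
  r11 <- rep(Rb[1, 1], n); r12 <- rep(Rb[1, 2], n); r13 <- rep(Rb[1, 3], n)
  r21 <- rep(Rb[2, 1], n); r22 <- rep(Rb[2, 2], n); r23 <- rep(Rb[2, 3], n)
  r31 <- rep(Rb[3, 1], n); r32 <- rep(Rb[3, 2], n); r33 <- rep(Rb[3, 3], n)
  px <- rep(pb[1], n); py <- rep(pb[2], n); pz <- rep(pb[3], n)
  for (i in seq_along(chain$links)) {
    l <- chain$links[[i]]
    th <- l$theta0 + Q[, i]
    ct <- cos(th); st <- sin(th)
    ca <- cos(l$alpha); sa <- sin(l$alpha)
    # link rotation columns: c1 = (ct, st, 0), c2 = (-st ca, ct ca, sa),
    # c3 = (st sa, -ct sa, ca); link translation (a ct, a st, d)
    tx <- l$a * ct; ty <- l$a * st; tz <- l$d
    px <- px + r11 * tx + r12 * ty + r13 * tz
    py <- py + r21 * tx + r22 * ty + r23 * tz
    pz <- pz + r31 * tx + r32 * ty + r33 * tz
    n11 <- r11 * ct + r12 * st
    n21 <- r21 * ct + r22 * st
    n31 <- r31 * ct + r32 * st
    n12 <- -r11 * st * ca + r12 * ct * ca + r13 * sa
    n22 <- -r21 * st * ca + r22 * ct * ca + r23 * sa
    n32 <- -r31 * st * ca + r32 * ct * ca + r33 * sa
    n13 <- r11 * st * sa - r12 * ct * sa + r13 * ca
    n23 <- r21 * st * sa - r22 * ct * sa + r23 * ca
    n33 <- r31 * st * sa - r32 * ct * sa + r33 * ca
    r11 <- n11; r12 <- n12; r13 <- n13
    r21 <- n21; r22 <- n22; r23 <- n23
    r31 <- n31; r32 <- n32; r33 <- n33
  }
  cbind(x = px, y = py, z = pz)
}

#' Spatial Jacobian of a revolute chain
#'
#' Columns are `(z_i x (p_e - p_i), z_i)` in the base/world frame, where
#' `z_i` and `p_i` are the axis and origin of joint i.
#'
#' @param chain A [dh_chain()].
#' @param q Joint angles (rad).
#' @return A 6 x n matrix (linear velocity rows first, then angular).
#' @export
jacobian <- function(chain, q) {
  stopifnot(inherits(chain, "dh_chain"), length(q) == length(chain$links))
  n <- length(chain$links)
  Ts <- vector("list", n + 1)
  Ts[[1]] <- chain$base
  for (i in seq_len(n)) {
    Ts[[i + 1]] <- rt_compose(Ts[[i]], dh_transform(chain$links[[i]], q[i]))
  }
  pe <- Ts[[n + 1]]$p
  J <- matrix(0, 6, n)
  for (i in seq_len(n)) {
    zi <- Ts[[i]]$R[, 3]
    pi_ <- Ts[[i]]$p
    r <- pe - pi_
    J[1:3, i] <- c(zi[2] * r[3] - zi[3] * r[2],
                   zi[3] * r[1] - zi[1] * r[3],
                   zi[1] * r[2] - zi[2] * r[1])
    J[4:6, i] <- zi
  }
  J
}

#' Numerical inverse kinematics (damped least squares)
#'
#' Iterates `dq = (J'J + lambda^2 I)^-1 J' e` on the 6-vector pose error
#' (translation mm, rotation as the axis-angle log), clamping each iterate
#' to the joint limits. Converges when both position and orientation errors
#' are under tolerance; otherwise raises an unreachable-pose error carrying
#' the best residual reached.
#'
#' @param chain A [dh_chain()].
#' @param target Target pose (`rigid_transform`).
#' @param seed_q Starting joint angles (default mid-range).
#' @param pos_tol Position tolerance, mm (default 1e-6).
#' @param rot_tol Orientation tolerance, rad (default 1e-8).
#' @param max_iter Iteration cap per start (default 200).
#' @param lambda Initial damping factor (default 0.1).
#' @param restarts Deterministic perturbed restarts tried on stagnation
#'   (default 5).
#' @return A list: `q` (joint angles), `iterations`, `pos_error_mm`,
#'   `rot_error_rad`.
#' @export
inverse_kinematics <- function(chain, target, seed_q = NULL,
                               pos_tol = 1e-6, rot_tol = 1e-8,
                               max_iter = 200, lambda = 0.1, restarts = 5) {
  stopifnot(inherits(chain, "dh_chain"), inherits(target, "rigid_transform"))
  n <- length(chain$links)
  lims <- do.call(rbind, lapply(chain$links, function(l) l$limits))
  q0 <- if (is.null(seed_q)) rowMeans(lims) else as.numeric(seed_q)
  stopifnot(length(q0) == n)
  # quick reachability screen: max reach from base along the chain
  reach <- sum(vapply(chain$links, function(l) abs(l$a) + abs(l$d), numeric(1)))
  tdist <- sqrt(sum((target$p - chain$base$p)^2))
  if (tdist > reach + pos_tol) {
    stop(sprintf("unreachable pose: target %.2f mm from base exceeds reach %.2f mm",
                 tdist, reach))
  }
  w_rot <- 100   # mm per rad: balances rotation rows against translation
  pose_err <- function(q) {
    Tq <- forward_kinematics(chain, q)
    c(target$p - Tq$p, w_rot * rotation_log(target$R %*% t(Tq$R)))
  }
  solve_from <- function(q) {
    lam <- lambda
    e <- pose_err(q)
    best_state <- NULL
    best <- Inf
    for (it in seq_len(max_iter)) {
      err_pos <- sqrt(sum(e[1:3]^2)); err_rot <- sqrt(sum(e[4:6]^2)) / w_rot
      score <- sqrt(sum(e^2))
      if (score < best) {
        best <- score
        best_state <- list(q = q, iterations = it, pos_error_mm = err_pos,
                           rot_error_rad = err_rot)
      }
      if (err_pos < pos_tol && err_rot < rot_tol) {
        return(list(done = TRUE, q = q, iterations = it,
                    pos_error_mm = err_pos, rot_error_rad = err_rot))
      }
      J <- jacobian(chain, q)
      J[4:6, ] <- w_rot * J[4:6, ]
      # Levenberg: shrink damping while steps improve, grow when they do not
      improved <- FALSE
      for (try in 1:10) {
        dq <- tryCatch(
          as.numeric(solve(crossprod(J) + lam^2 * diag(n), crossprod(J, e))),
          error = function(err) rep(0, n))
        q_new <- pmin(pmax(q + dq, lims[, 1]), lims[, 2])
        e_new <- pose_err(q_new)
        if (sqrt(sum(e_new^2)) < score || max(abs(dq)) < 1e-15) {
          q <- q_new; e <- e_new
          lam <- max(lam * 0.5, 1e-10)
          improved <- TRUE
          break
        }
        lam <- lam * 4
      }
      if (!improved) break
    }
    c(list(done = FALSE), best_state)
  }
  overall_best <- NULL
  starts <- list(q0)
  # deterministic perturbed restarts around the seed
  offs <- withr::with_seed(1L, replicate(restarts, stats::runif(n, -1, 1),
                                         simplify = FALSE))
  for (k in seq_len(restarts)) {
    starts[[k + 1]] <- pmin(pmax(q0 + offs[[k]] * k / 2, lims[, 1]), lims[, 2])
  }
  total_it <- 0
  for (s in starts) {
    res <- solve_from(s)
    total_it <- total_it + res$iterations
    if (res$done) {
      return(list(q = res$q, iterations = total_it,
                  pos_error_mm = res$pos_error_mm,
                  rot_error_rad = res$rot_error_rad))
    }
    if (is.null(overall_best) ||
        res$pos_error_mm + res$rot_error_rad <
          overall_best$pos_error_mm + overall_best$rot_error_rad) {
      overall_best <- res
    }
  }
  stop(sprintf(
    "unreachable pose: no convergence after %d iterations (best residual %.3g mm, %.3g rad)",
    total_it, overall_best$pos_error_mm, overall_best$rot_error_rad))
}

#' Default six-axis bioprinting manipulator
#'
#' A representative anthropomorphic 6R arm with a spherical wrist and about
#' 600 mm reach: the shipped stand-in for the physical arm's kinematic table,
#' fully overridable from YAML ([read_chain_yaml()]). All algorithms are
#' parameter-generic.
#'
#' @return A [dh_chain()].
#' @export
default_chain <- function() {
  dh_chain(list(
    dh_link(a = 0,   alpha = pi / 2,  d = 180, theta0 = 0,      limits = c(-pi, pi)),
    dh_link(a = 250, alpha = 0,       d = 0,   theta0 = 0,      limits = c(-2.2, 2.2)),
    dh_link(a = 60,  alpha = pi / 2,  d = 0,   theta0 = pi / 2, limits = c(-2.6, 2.6)),
    dh_link(a = 0,   alpha = -pi / 2, d = 230, theta0 = 0,      limits = c(-pi, pi)),
    dh_link(a = 0,   alpha = pi / 2,  d = 0,   theta0 = 0,      limits = c(-2.0, 2.0)),
    dh_link(a = 0,   alpha = 0,       d = 80,  theta0 = 0,      limits = c(-pi, pi))
  ))
}

#' Read / write a kinematic chain as YAML
#'
#' The YAML schema is a list `links:` of maps with keys `a`, `alpha`, `d`,
#' `theta0`, `limits` (two numbers), plus optional `base` (16 numbers,
#' row-major homogeneous matrix).
#'
#' @param path File path.
#' @return A [dh_chain()].
#' @export
read_chain_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  if (is.null(obj$links)) stop("chain YAML must have a 'links' list")
  links <- lapply(obj$links, function(l) {
    dh_link(a = l$a %||% 0, alpha = l$alpha %||% 0, d = l$d %||% 0,
            theta0 = l$theta0 %||% 0,
            limits = as.numeric(l$limits %||% c(-pi, pi)))
  })
  base <- if (!is.null(obj$base)) {
    rt_from_matrix(matrix(as.numeric(obj$base), 4, 4, byrow = TRUE), tol = 1e-6)
  } else rt_identity()
  dh_chain(links, base)
}

#' @param chain A [dh_chain()] to serialize.
#' @rdname read_chain_yaml
#' @export
write_chain_yaml <- function(chain, path) {
  stopifnot(inherits(chain, "dh_chain"))
  obj <- list(
    convention = "standard (distal) Denavit-Hartenberg; mm and radians",
    links = lapply(chain$links, function(l) {
      list(a = l$a, alpha = l$alpha, d = l$d, theta0 = l$theta0,
           limits = l$limits)
    }),
    base = as.numeric(t(rt_as_matrix(chain$base)))
  )
  yaml::write_yaml(obj, path, precision = 12)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
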