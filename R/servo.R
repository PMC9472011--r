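# Discrete-time closed-loop visual tracking simulator.
#
# The robot holds a preset printing path expressed relative to the wound's
# initial pose. A camera measures the wound pose (from n >= 3 markers) every
# camera period, with a fixed pipeline latency in frames; each control step
# the controller composes the latest measured displacement with the preset
# pose (pure feed-forward compensation — the compensation is the measured
# disturbance itself, no PID refinement) and the end-effector moves toward
# the compensated pose under a speed limit. Tracking error is the distance
# between the commanded pose and the true compensated pose.

#' Target trajectory generator
#'
#' Three laboratory motions used to characterize tracking: a `square`
#' (constant speed along the perimeter, sharp corners), a `circle`
#' (constant angular rate), and a `shaker` (circular translation with a
#' continuously rotating target frame: a fixed point on a rotating shaker
#' plate).
#'
#' @param kind `"square"`, `"circle"` or `"shaker"`.
#' @param speed Path speed, mm/s (>= 0).
#' @param duration Duration, s.
#' @param dt Sample period, s.
#' @param side Square side length, mm.
#' @param radius Circle/shaker radius, mm.
#' @param center Trajectory centre, length-3 (mm).
#' @param spin_rate Shaker frame spin rate, rad/s.
#' @return A tibble of class `target_trajectory`: `t` (s), `x`, `y`, `z`
#'   (mm), `yaw`, `pitch`, `roll` (rad), `turn` (per-step heading change,
#'   rad).
#' @export
make_trajectory <- function(kind = c("square", "circle", "shaker"),
                            speed, duration, dt = 0.01,
                            side = 40, radius = 20, center = c(0, 0, 0),
                            spin_rate = pi / 4) {
  kind <- match.arg(kind)
  stopifnot(speed >= 0, duration > 0, dt > 0)
  t <- seq(0, duration, by = dt)
  if (kind == "square") {
    per <- 4 * side
    s <- (speed * t) %% per
    leg <- pmin(floor(s / side), 3)
    u <- s - leg * side
    x <- ifelse(leg == 0, u, ifelse(leg == 1, side, ifelse(leg == 2, side - u, 0)))
    y <- ifelse(leg == 0, 0, ifelse(leg == 1, u, ifelse(leg == 2, side, side - u)))
    x <- x - side / 2 + center[1]
    y <- y - side / 2 + center[2]
    z <- rep(center[3], length(t))
    yaw <- rep(0, length(t))
  } else {
    omega <- if (radius > 0) speed / radius else 0
    ang <- omega * t
    x <- center[1] + radius * cos(ang)
    y <- center[2] + radius * sin(ang)
    z <- rep(center[3], length(t))
    yaw <- if (kind == "shaker") spin_rate * t else rep(0, length(t))
  }
  dx <- diff(x); dy <- diff(y)
  heading <- atan2(dy, dx)
  turn <- c(0, abs(wrap_angle(diff(heading))), 0)
  if (length(turn) != length(t)) turn <- rep(0, length(t))
  structure(tibble::tibble(t = t, x = x, y = y, z = z,
                           yaw = yaw, pitch = 0, roll = 0, turn = turn),
            class = c("target_trajectory", class(tibble::tibble())),
            kind = kind, speed = speed, dt = dt, side = side,
            radius = radius, center = center, spin_rate = spin_rate,
            duration = duration)
}

wrap_angle <- function(a) atan2(sin(a), cos(a))

#' Servo loop configuration
#'
#' Image acquisition and manipulator control cycles are synchronized: the
#' camera period must be an integer multiple of the control period. Defaults
#' are a 30 Hz camera with one frame of pipeline latency driving a 90 Hz
#' control loop — declared assumptions, not measured values.
#'
#' @param control_period Control step, s.
#' @param camera_period Camera frame period, s (integer multiple of
#'   `control_period`).
#' @param latency_frames Measurement pipeline latency in camera frames.
#' @param noise_pos_sd Marker position noise, mm.
#' @param max_speed End-effector speed limit, mm/s.
#' @param max_accel End-effector acceleration limit, mm/s^2. Finite
#'   acceleration is what makes sharp corners the dominant error source: a
#'   corner demands a discontinuous velocity direction change the arm cannot
#'   deliver.
#' @param marker_count Markers defining the wound plane (n >= 3).
#' @param marker_radius Marker ring radius, mm.
#' @return A list of class `servo_config`.
#' @export
servo_config <- function(control_period = 1 / 90, camera_period = 1 / 30,
                         latency_frames = 1L, noise_pos_sd = 0,
                         max_speed = 500, max_accel = 400,
                         marker_count = 4L, marker_radius = 15) {
  stopifnot(control_period > 0, camera_period > 0, latency_frames >= 0,
            noise_pos_sd >= 0, max_speed > 0, max_accel > 0, marker_count >= 3)
  ratio <- camera_period / control_period
  if (abs(ratio - round(ratio)) > 1e-9) {
    stop("camera_period must be an integer multiple of control_period")
  }
  structure(list(control_period = control_period,
                 camera_period = camera_period,
                 latency_frames = as.integer(latency_frames),
                 noise_pos_sd = noise_pos_sd,
                 max_speed = max_speed,
                 max_accel = max_accel,
                 marker_count = as.integer(marker_count),
                 marker_radius = marker_radius),
            class = "servo_config")
}

# marker model: ring of n points in the target frame (z = 0 plane)
marker_model <- function(cfg) {
  n <- cfg$marker_count
  ang <- 2 * pi * (seq_len(n) - 1) / n
  cbind(cfg$marker_radius * cos(ang), cfg$marker_radius * sin(ang), 0)
}

#' Measure a target pose from noisy markers
#'
#' The wound is treated as a rigid body carrying n >= 3 markers. Marker
#' world positions are perturbed by isotropic Gaussian noise; the pose is
#' re-estimated by fitting a plane through the markers (orientation) plus
#' 2D registration inside the plane (in-plane angle and position).
#'
#' @param pose True target pose (`rigid_transform`).
#' @param cfg A [servo_config()].
#' @param markers Optional k x 3 marker coordinates in the target frame.
#' @return Estimated pose (`rigid_transform`).
#' @export
measure_target <- function(pose, cfg, markers = NULL) {
  stopifnot(inherits(pose, "rigid_transform"), inherits(cfg, "servo_config"))
  M <- if (is.null(markers)) marker_model(cfg) else as.matrix(markers)
  if (nrow(M) < 3) stop("degenerate marker placement: need >= 3 markers")
  W <- rt_apply(pose, M)
  if (cfg$noise_pos_sd > 0) {
    W <- W + matrix(stats::rnorm(length(W), 0, cfg$noise_pos_sd), nrow(W), 3)
  }
  pl <- fit_plane(W)  # errors on collinear markers
  z <- pl$normal
  # model-plane frame (markers assumed coplanar in target z = 0)
  plm <- fit_plane(M)
  zm <- plm$normal
  cw <- colMeans(W); cm <- colMeans(M)
  bw <- plane_basis(z); bm <- plane_basis(zm)
  Uw <- (W - matrix(cw, nrow(W), 3, byrow = TRUE)) %*% bw
  Um <- (M - matrix(cm, nrow(M), 3, byrow = TRUE)) %*% bm
  # 2D Kabsch for the in-plane angle
  H <- crossprod(Um, Uw)
  ang <- atan2(H[1, 2] - H[2, 1], H[1, 1] + H[2, 2])
  R2 <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
  # rotation mapping target frame to world: world basis * R2 * t(model basis)
  Bw <- cbind(bw, z)
  Bm <- cbind(bm, zm)
  R <- Bw %*% rbind(cbind(R2, c(0, 0)), c(0, 0, 1)) %*% t(Bm)
  R <- project_SO3(R)
  p <- cw - as.numeric(R %*% cm)
  rigid_transform(R, p, tol = 1e-6)
}

# deterministic in-plane orthonormal basis for a unit normal
plane_basis <- function(z) {
  a <- if (abs(z[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  x <- a - sum(a * z) * z
  x <- x / sqrt(sum(x^2))
  y <- c(z[2] * x[3] - z[3] * x[2],
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  cbind(x, y)
}

#' Simulate closed-loop visual tracking
#'
#' Steps the servo loop along a target trajectory. Each camera frame (with
#' pipeline latency) yields a measured target displacement relative to the
#' target's initial pose; each control step the commanded pose moves toward
#' preset-composed-with-latest-displacement under the speed limit. The
#' returned trace is fully recomputable: error = distance between commanded
#' and true compensated positions. Runs are bit-reproducible for a given
#' seed.
#'
#' @param traj A [make_trajectory()] result.
#' @param cfg A [servo_config()].
#' @param preset Preset pose relative to the target frame (default
#'   identity: track the target itself).
#' @param seed Integer seed for measurement noise.
#' @return A tibble of class `tracking_trace`: time, target / measured /
#'   commanded positions, `error_mm`, `segment` (`"straight"` or
#'   `"corner"`).
#' @export
simulate_tracking <- function(traj, cfg = servo_config(), preset = rt_identity(),
                              seed = 1L) {
  stopifnot(inherits(traj, "target_trajectory"), inherits(cfg, "servo_config"),
            inherits(preset, "rigid_transform"))
  dt <- cfg$control_period
  duration <- attr(traj, "duration")
  steps <- floor(duration / dt)
  every <- round(cfg$camera_period / dt)

  kind <- attr(traj, "kind"); speed <- attr(traj, "speed")
  side <- attr(traj, "side"); radius <- attr(traj, "radius")
  center <- attr(traj, "center"); spin <- attr(traj, "spin_rate")
  # analytic target pose (avoids lookup quantization at the control rate)
  pose_at <- function(tt) {
    if (kind == "square") {
      per <- 4 * side
      s <- (speed * tt) %% per
      leg <- min(floor(s / side), 3)
      u <- s - leg * side
      xy <- switch(as.character(leg),
                   "0" = c(u, 0), "1" = c(side, u),
                   "2" = c(side - u, side), "3" = c(0, side - u))
      rigid_transform(diag(3), c(xy[1] - side / 2 + center[1],
                                 xy[2] - side / 2 + center[2], center[3]))
    } else {
      omega <- if (radius > 0) speed / radius else 0
      ang <- omega * tt
      yaw <- if (kind == "shaker") spin * tt else 0
      rigid_transform(euler_to_rotation(yaw, 0, 0),
                      c(center[1] + radius * cos(ang),
                        center[2] + radius * sin(ang), center[3]), tol = 1e-6)
    }
  }
  # did the path turn a corner during (tt - dt, tt]?
  turn_at <- function(tt) {
    if (kind != "square" || speed == 0) return(0)
    s1 <- speed * (tt - dt); s2 <- speed * tt
    leg1 <- floor(s1 / attr(traj, "side"))
    leg2 <- floor(s2 / attr(traj, "side"))
    if (leg2 > leg1) pi / 2 else 0
  }
  pose0 <- pose_at(0)
  inv_pose0 <- rt_inverse(pose0)

  run <- function() {
    meas_buf <- list()         # queue of camera measurements
    latest <- pose0            # latest available measurement (after latency)
    commanded <- rt_compose(pose0, preset)
    vel <- c(0, 0, 0)          # end-effector velocity state (mm/s)
    rows <- vector("list", steps)
    stale <- Inf               # seconds since last direction change reached us
    for (k in seq_len(steps)) {
      tt <- k * dt
      if ((k - 1) %% every == 0) {
        meas_buf[[length(meas_buf) + 1]] <- measure_target(pose_at(tt), cfg)
        if (length(meas_buf) > cfg$latency_frames) {
          latest <- meas_buf[[1]]
          meas_buf <- meas_buf[-1]
        }
      }
      disp <- rt_compose(latest, inv_pose0)
      desired <- rt_compose(disp, rt_compose(pose0, preset))
      # velocity command toward the compensated pose, under accel/speed caps
      v_des <- (desired$p - commanded$p) / dt
      dv <- v_des - vel
      dv_len <- sqrt(sum(dv^2))
      dv_max <- cfg$max_accel * dt
      if (dv_len > dv_max) dv <- dv / dv_len * dv_max
      vel <- vel + dv
      v_len <- sqrt(sum(vel^2))
      if (v_len > cfg$max_speed) vel <- vel / v_len * cfg$max_speed
      commanded <- rigid_transform(desired$R, commanded$p + vel * dt, tol = 1e-6)
      truth <- rt_compose(rt_compose(pose_at(tt), inv_pose0),
                          rt_compose(pose0, preset))
      err <- sqrt(sum((commanded$p - truth$p)^2))
      # corner window: stale-measurement interval after a sharp turn plus
      # the re-acceleration time of the velocity direction swing
      if (turn_at(tt) > pi / 4) stale <- 0 else stale <- stale + dt
      corner_win <- cfg$latency_frames * cfg$camera_period + cfg$camera_period +
        speed * sqrt(2) / cfg$max_accel + 2 * dt
      seg <- if (stale <= corner_win) "corner" else "straight"
      rows[[k]] <- c(tt, truth$p, latest$p, commanded$p, err,
                     seg == "corner")
    }
    do.call(rbind, rows)
  }
  m <- withr::with_seed(as.integer(seed), run())
  out <- tibble::tibble(
    t = m[, 1],
    target_x = m[, 2], target_y = m[, 3], target_z = m[, 4],
    measured_x = m[, 5], measured_y = m[, 6], measured_z = m[, 7],
    commanded_x = m[, 8], commanded_y = m[, 9], commanded_z = m[, 10],
    error_mm = m[, 11],
    segment = ifelse(m[, 12] > 0, "corner", "straight")
  )
  structure(out, class = c("tracking_trace", class(tibble::tibble())),
            kind = attr(traj, "kind"), speed = attr(traj, "speed"),
            seed = as.integer(seed))
}

#' Summary statistics of a tracking trace
#'
#' @param trace A `tracking_trace`.
#' @param transient Initial settle time excluded from statistics, s
#'   (default 0.5).
#' @return A tibble: one row overall plus one per segment label, with
#'   `max_mm`, `mean_mm`, `rms_mm`, `n`.
#' @export
error_stats <- function(trace, transient = 0.5) {
  stopifnot(inherits(trace, "tracking_trace"))
  tr <- trace[trace$t > transient, ]
  if (nrow(tr) == 0) stop("empty trace (or all samples inside the transient window)")
  overall <- tibble::tibble(segment = "all",
                            max_mm = max(tr$error_mm),
                            mean_mm = mean(tr$error_mm),
                            rms_mm = sqrt(mean(tr$error_mm^2)),
                            n = nrow(tr))
  per <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(tr), .data$segment),
    max_mm = max(.data$error_mm), mean_mm = mean(.data$error_mm),
    rms_mm = sqrt(mean(.data$error_mm^2)), n = dplyr::n(), .groups = "drop")
  dplyr::bind_rows(overall, per)
}

#' Export a tracking trace as CSV
#' @param trace A `tracking_trace`.
#' @param file Output CSV path.
#' @export
write_trace_csv <- function(trace, file) {
  stopifnot(inherits(trace, "tracking_trace"))
  utils::write.csv(tibble::as_tibble(trace), file, row.names = FALSE)
  invisible(file)
}
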