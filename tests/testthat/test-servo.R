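test_that("trajectory constructors satisfy their geometric definitions", {
  # circle: constant radius, constant arc step
  tr <- make_trajectory("circle", speed = 10, duration = 5, dt = 0.01,
                        radius = 20)
  r <- sqrt(tr$x^2 + tr$y^2)
  expect_lt(max(abs(r - 20)), 1e-9)
  arc <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
  expect_lt(max(abs(arc - 10 * 0.01)), 1e-5)

  # square: loop time = perimeter / speed
  sq <- make_trajectory("square", speed = 16, duration = 10.1, dt = 0.005,
                        side = 40)
  loop_t <- 4 * 40 / 16
  i0 <- 1; i1 <- which.min(abs(sq$t - loop_t))
  expect_lt(sqrt((sq$x[i1] - sq$x[i0])^2 + (sq$y[i1] - sq$y[i0])^2), 0.2)

  # shaker: circular translation and strictly monotone orientation
  sh <- make_trajectory("shaker", speed = 10, duration = 5, radius = 15)
  expect_lt(max(abs(sqrt(sh$x^2 + sh$y^2) - 15)), 1e-9)
  expect_true(all(diff(sh$yaw) > 0))

  expect_error(make_trajectory("zigzag", 10, 1), "arg")
})

test_that("noiseless zero-latency measurement is exact", {
  cfg <- servo_config(noise_pos_sd = 0)
  pose <- rigid_transform(euler_to_rotation(0.4, 0.2, -0.1), c(5, -3, 8))
  m <- measure_target(pose, cfg)
  expect_rt_equal(m, pose, tol = 1e-9)
})

test_that("collinear markers are rejected", {
  cfg <- servo_config()
  pose <- rt_identity()
  line <- cbind(1:5, 0, 0)
  expect_error(measure_target(pose, cfg, markers = line), "degenerate")
  expect_error(measure_target(pose, cfg, markers = cbind(1:2, 0, 0)),
               "degenerate")
})

test_that("measured pose error RMS matches least-squares propagation within 20%", {
  cfg <- servo_config(noise_pos_sd = 0.1, marker_count = 4)
  pose <- rigid_transform(euler_to_rotation(0.3, 0.1, -0.2), c(5, 8, 2))
  set.seed(91)
  errs <- replicate(3000, {
    m <- measure_target(pose, cfg)
    sqrt(sum((m$p - pose$p)^2))
  })
  rms <- sqrt(mean(errs^2))
  oracle <- 0.1 * sqrt(3 / 4)   # centroid of 4 markers, 3 axes
  expect_lt(abs(rms - oracle) / oracle, 0.2)
})

test_that("a static target is tracked to numerical zero", {
  tr <- simulate_tracking(make_trajectory("circle", speed = 0, duration = 3),
                          servo_config(), seed = 1)
  expect_lt(max(tr$error_mm[tr$t > 1]), 1e-9)
})

test_that("max tracking error increases strictly with target speed", {
  cfg <- servo_config()
  mx <- sapply(c(5, 10, 15, 20, 30), function(v) {
    tr <- simulate_tracking(make_trajectory("circle", speed = v, duration = 6),
                            cfg, seed = 1)
    max(tr$error_mm[tr$t > 1])
  })
  expect_true(all(diff(mx) > 0))
  # latency lower bound: error >= speed x latency x camera period
  lb <- c(5, 10, 15, 20, 30) * cfg$latency_frames * cfg$camera_period
  expect_true(all(mx >= lb - 1e-9))
})

test_that("corner steps dominate the square-path error", {
  tr <- simulate_tracking(make_trajectory("square", speed = 15, duration = 12),
                          servo_config(), seed = 1)
  st <- error_stats(tr)
  corner <- st[st$segment == "corner", ]
  straight <- st[st$segment == "straight", ]
  expect_gt(corner$mean_mm, straight$mean_mm)
  expect_gt(corner$max_mm, straight$max_mm)
})

test_that("an ideal loop (no latency, no noise, unbounded actuation) tracks smooth paths exactly", {
  cfg <- servo_config(latency_frames = 0L, camera_period = 1 / 90,
                      max_speed = 1e6, max_accel = 1e9)
  tr <- simulate_tracking(make_trajectory("circle", speed = 20, duration = 4),
                          cfg, seed = 1)
  expect_lt(max(tr$error_mm[tr$t > 0.5]), 1e-9)
})

test_that("seeded runs are bit-reproducible and the trace is self-consistent", {
  cfg <- servo_config(noise_pos_sd = 0.05)
  traj <- make_trajectory("shaker", speed = 10, duration = 4)
  t1 <- simulate_tracking(traj, cfg, seed = 5)
  t2 <- simulate_tracking(traj, cfg, seed = 5)
  expect_identical(tibble::as_tibble(t1), tibble::as_tibble(t2))
  # error column recomputable from stored poses
  recomputed <- sqrt((t1$commanded_x - t1$target_x)^2 +
                       (t1$commanded_y - t1$target_y)^2 +
                       (t1$commanded_z - t1$target_z)^2)
  expect_lt(max(abs(recomputed - t1$error_mm)), 1e-9)
})

test_that("error_stats matches hand-computed values and rejects empty traces", {
  tr <- simulate_tracking(make_trajectory("circle", speed = 10, duration = 3),
                          servo_config(), seed = 1)
  st <- error_stats(tr, transient = 0.5)
  sel <- tr$error_mm[tr$t > 0.5]
  expect_equal(st$max_mm[st$segment == "all"], max(sel))
  expect_equal(st$mean_mm[st$segment == "all"], mean(sel))
  expect_equal(st$rms_mm[st$segment == "all"], sqrt(mean(sel^2)))
  expect_error(error_stats(tr, transient = 100), "empty trace")
})
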