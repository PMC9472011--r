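test_that("projection hits the principal point on the optical axis", {
  cam <- camera_model(fx = 1000, fy = 900, x0 = 320, y0 = 240)
  expect_equal(unname(project(cam, c(0, 0, 100))), c(320, 240))
})

test_that("projection matches the hand-evaluated pinhole formula", {
  cam <- camera_model(fx = 1000, fy = 1000, x0 = 320, y0 = 240, s = 0)
  uv <- project(cam, c(10, 0, 100))
  expect_equal(unname(uv[1]), 320 + 1000 * 10 / 100)   # = 420
  expect_equal(unname(uv[2]), 240)
  # skew contributes s*y/z to u
  cam2 <- camera_model(fx = 1000, fy = 1000, x0 = 320, y0 = 240, s = 10)
  uv2 <- project(cam2, c(10, 20, 100))
  expect_equal(unname(uv2[1]), 320 + (1000 * 10 + 10 * 20) / 100)
})

test_that("points behind the camera are rejected", {
  cam <- camera_model(1000, 1000, 320, 240)
  expect_error(project(cam, c(0, 0, -5)), "behind-camera")
  expect_error(project(cam, c(1, 1, 0)), "behind-camera")
})

test_that("noiseless triangulation round-trips to machine precision", {
  set.seed(21)
  rig <- make_stereo_rig(baseline = 60, fx = 1200)
  for (i in 1:20) {
    X <- c(stats::runif(1, -50, 50), stats::runif(1, -50, 50),
           stats::runif(1, 300, 700))
    tr <- triangulate(rig, project(rig$left, X), project(rig$right, X))
    expect_lt(sqrt(sum((tr$point - X)^2)), 1e-9)
    expect_lt(tr$reprojection_residual_px, 1e-6)
  }
})

test_that("triangulation flags parallel rays / coincident centers", {
  cam <- camera_model(1000, 1000, 320, 240)
  expect_error(stereo_rig(cam, cam), "coincident")
  # distinct centers but identical ray directions (pure baseline offset,
  # same pixel): rays are parallel
  rig <- make_stereo_rig(baseline = 60, fx = 1000)
  expect_error(triangulate(rig, c(320, 240), c(320, 240)), "degenerate")
})

test_that("noisy linear triangulation tracks the nonlinear oracle", {
  set.seed(22)
  rig <- make_stereo_rig(baseline = 60, fx = 1200)
  err_lin <- err_nl <- numeric(200)
  for (i in 1:200) {
    X <- c(stats::runif(1, -40, 40), stats::runif(1, -40, 40),
           stats::runif(1, 350, 650))
    nl <- stats::rnorm(2, 0, 0.5); nr <- stats::rnorm(2, 0, 0.5)
    uvl <- project(rig$left, X) + nl
    uvr <- project(rig$right, X) + nr
    err_lin[i] <- sqrt(sum((triangulate(rig, uvl, uvr)$point - X)^2))
    err_nl[i] <- sqrt(sum((triangulate_nonlinear(rig, uvl, uvr)$point - X)^2))
  }
  expect_lt(stats::median(err_lin), 2 * stats::median(err_nl))
  expect_gt(stats::median(err_lin), stats::median(err_nl) / 2)
})

test_that("recognition error metrics match hand evaluation and invariants", {
  e <- recognition_errors(l = 504, l0 = 500, dP = 0.8, theta = pi / 6)
  expect_equal(e$Ed, 0.008)
  expect_equal(e$Ea, atan(0.8 * sin(pi / 6) / 500))  # ~8.0e-4 rad
  expect_lt(abs(e$Ea - 8.0e-4), 1e-6)

  expect_equal(recognition_errors(500, 500, 1, 0.3)$Ed, 0)
  expect_equal(recognition_errors(510, 500, 0, 0.3)$Ea, 0)
  expect_error(recognition_errors(500, 0, 1, 0.3), "l0")
})

test_that("Ed and Ea are monotone in range error and planar error", {
  l0 <- 500
  Ed <- recognition_errors(l = l0 + seq(0, 10, by = 0.5), l0 = l0,
                           dP = 1, theta = pi / 4)$Ed
  expect_true(all(diff(Ed) > 0))
  Ea <- recognition_errors(l = l0, l0 = l0, dP = seq(0, 5, by = 0.25),
                           theta = pi / 4)$Ea
  expect_true(all(diff(Ea) > 0))
})

test_that("project/triangulate round trip stays below 1e-6 px over 1000 points", {
  set.seed(23)
  rig <- make_stereo_rig(baseline = 80, fx = 1000)
  worst <- 0
  for (i in 1:1000) {
    X <- c(stats::runif(1, -60, 60), stats::runif(1, -60, 60),
           stats::runif(1, 250, 800))
    tr <- triangulate(rig, project(rig$left, X), project(rig$right, X))
    worst <- max(worst, tr$reprojection_residual_px)
  }
  expect_lt(worst, 1e-6)
})
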