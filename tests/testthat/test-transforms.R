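test_that("compose handles identity and inverse", {
  set.seed(11)
  T1 <- random_rt()
  expect_rt_equal(rt_compose(T1, rt_identity()), T1, tol = 1e-12)
  expect_rt_equal(rt_compose(rt_identity(), T1), T1, tol = 1e-12)
  expect_rt_equal(rt_compose(T1, rt_inverse(T1)), rt_identity(), tol = 1e-12)
  expect_rt_equal(rt_compose(rt_inverse(T1), T1), rt_identity(), tol = 1e-12)
})

test_that("compose matches the 4x4 matrix-product oracle on random pairs", {
  set.seed(12)
  for (i in 1:50) {
    a <- random_rt(); b <- random_rt()
    expect_lt(max_mat_diff(rt_as_matrix(rt_compose(a, b)),
                           compose_oracle(a, b)), 1e-12)
  }
})

test_that("group axioms hold numerically (associativity on random triples)", {
  set.seed(13)
  for (i in 1:30) {
    a <- random_rt(); b <- random_rt(); c <- random_rt()
    expect_rt_equal(rt_compose(rt_compose(a, b), c),
                    rt_compose(a, rt_compose(b, c)), tol = 1e-9)
  }
})

test_that("rigid_transform rejects improper rotations", {
  expect_error(rigid_transform(diag(c(1, 1, -1))), "rotation")
  expect_error(rigid_transform(matrix(1, 3, 3)), "rotation")
})

test_that("euler conversion: axis cases and identity", {
  expect_lt(max_mat_diff(euler_to_rotation(0, 0, 0), diag(3)), 1e-15)
  # yaw pi/2 maps x-hat to y-hat
  R <- euler_to_rotation(pi / 2, 0, 0)
  expect_lt(max(abs(R %*% c(1, 0, 0) - c(0, 1, 0))), 1e-12)
  # pitch pi/2 maps x-hat to -z-hat
  R <- euler_to_rotation(0, pi / 2, 0)
  expect_lt(max(abs(R %*% c(1, 0, 0) - c(0, 0, -1))), 1e-12)
})

test_that("euler round-trip reproduces the rotation away from gimbal lock", {
  set.seed(14)
  worst <- 0
  for (i in 1:1000) {
    e <- c(stats::runif(1, -pi, pi),
           stats::runif(1, -pi / 2 + 1e-3, pi / 2 - 1e-3),
           stats::runif(1, -pi, pi))
    R <- euler_to_rotation(e[1], e[2], e[3])
    b <- rotation_to_euler(R)
    expect_false(b$gimbal_lock)
    R2 <- euler_to_rotation(b$yaw, b$pitch, b$roll)
    worst <- max(worst, max_mat_diff(R, R2))
  }
  expect_lt(worst, 1e-9)
})

test_that("gimbal lock is flagged near pitch = pi/2", {
  R <- euler_to_rotation(0.4, pi / 2, 0)
  e <- rotation_to_euler(R)
  expect_true(e$gimbal_lock)
  # the rotation itself is still reproduced
  expect_lt(max_mat_diff(euler_to_rotation(e$yaw, e$pitch, e$roll), R), 1e-9)
})

test_that("fit_plane recovers exact planes and flags degeneracy", {
  p <- fit_plane(rbind(c(0, 0, 5), c(1, 0, 5), c(0, 1, 5)))
  expect_lt(max(abs(p$normal - c(0, 0, 1))), 1e-12)
  expect_lt(abs(p$d - 5), 1e-12)

  set.seed(15)
  n <- stats::rnorm(3); n <- n / sqrt(sum(n^2)); if (n[3] < 0) n <- -n
  d <- stats::runif(1, -10, 10)
  b1 <- c(n[2], -n[1], 0); b1 <- b1 / sqrt(sum(b1^2))
  b2 <- c(n[2] * b1[3] - n[3] * b1[2], n[3] * b1[1] - n[1] * b1[3],
          n[1] * b1[2] - n[2] * b1[1])
  uv <- matrix(stats::runif(200, -5, 5), 100, 2)
  pts <- d * matrix(n, 100, 3, byrow = TRUE) +
    uv[, 1] %o% b1 + uv[, 2] %o% b2
  p2 <- fit_plane(pts)
  # sine of the angle between normals (acos loses precision near 0)
  cr <- c(p2$normal[2] * n[3] - p2$normal[3] * n[2],
          p2$normal[3] * n[1] - p2$normal[1] * n[3],
          p2$normal[1] * n[2] - p2$normal[2] * n[1])
  expect_lt(sqrt(sum(cr^2)), 1e-9)

  expect_error(fit_plane(rbind(c(0, 0, 0), c(1, 1, 1))), "degenerate")
  line <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(fit_plane(line), "degenerate")
})

test_that("fit_plane is optimal against random candidate planes", {
  set.seed(16)
  pts <- cbind(stats::runif(40, -5, 5), stats::runif(40, -5, 5),
               stats::rnorm(40, sd = 0.3))
  p <- fit_plane(pts)
  res <- function(n, d) sqrt(mean((pts %*% n - d)^2))
  best <- res(p$normal, p$d)
  for (i in 1:1000) {
    n <- stats::rnorm(3); n <- n / sqrt(sum(n^2))
    d <- mean(pts %*% n)
    expect_gte(res(n, d), best - 1e-12)
  }
})

test_that("transform JSON round-trips with convention header", {
  set.seed(17)
  T1 <- random_rt()
  f <- tempfile(fileext = ".json")
  write_transforms_json(list(a = T1), f)
  back <- read_transforms_json(f)
  expect_rt_equal(back$a, T1, tol = 1e-12)
  expect_match(paste(readLines(f), collapse = ""), "Z-Y-X")
})
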