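make_truth <- function() {
  list(X = rigid_transform(euler_to_rotation(0.2, 0.1, -0.3), c(10, -5, 30)),
       G = rigid_transform(euler_to_rotation(-0.5, 0.2, 0.9), c(100, 50, -20)))
}

test_that("noiseless 10-pose fixture recovers H_ce to machine precision", {
  tr <- make_truth()
  samples <- gen_handeye_set(tr$X, tr$G, n = 10, seed = 3)
  sol <- handeye_solve(samples)
  expect_lt(rotation_distance(sol$H_ce$R, tr$X$R), 1e-8)
  expect_lt(sqrt(sum((sol$H_ce$p - tr$X$p)^2)), 1e-8)
  expect_lt(rotation_distance(sol$H_gw$R, tr$G$R), 1e-7)
  expect_lt(sqrt(sum((sol$H_gw$p - tr$G$p)^2)), 1e-7)
  expect_lt(max(sol$residuals$translation_mm), 1e-9)
})

test_that("single-axis motion is refused with a degenerate-motion error", {
  tr <- make_truth()
  ax <- c(0, 0, 1)
  samples <- lapply(1:6, function(i) {
    H_ew <- rigid_transform(woundpath:::axis_angle_rotation(ax, 0.3 * i),
                            c(10 * i, 0, 5))
    H_cg <- rt_compose(rt_inverse(tr$G), rt_compose(H_ew, tr$X))
    handeye_sample(H_ew, H_cg)
  })
  expect_error(handeye_solve(samples), "degenerate motion")
  expect_error(handeye_solve(samples[1:2]), "at least 3")
})

test_that("identity problem returns the identity solution", {
  samples <- gen_handeye_set(rt_identity(), rt_identity(), n = 8, seed = 4)
  sol <- handeye_solve(samples)
  expect_rt_equal(sol$H_ce, rt_identity(), tol = 1e-8)
  expect_rt_equal(sol$H_gw, rt_identity(), tol = 1e-8)
})

test_that("residuals localize a corrupted sample", {
  tr <- make_truth()
  samples <- gen_handeye_set(tr$X, tr$G, n = 10, seed = 5)
  bad <- samples[[7]]
  samples[[7]] <- handeye_sample(
    bad$H_ew, rt_compose(bad$H_cg,
                         rigid_transform(euler_to_rotation(0.05, 0, 0), c(2, 0, 0))))
  sol <- handeye_solve(samples[-7])  # solve on clean samples
  res <- handeye_residuals(samples, sol)
  expect_equal(which.max(res$translation_mm), 7)
  expect_equal(which.max(res$rotation_rad), 7)
})

test_that("a pure 1 mm translation perturbation shows up as ~1 mm translation residual", {
  tr <- make_truth()
  samples <- gen_handeye_set(tr$X, tr$G, n = 10, seed = 6)
  p <- samples[[4]]
  samples[[4]] <- handeye_sample(
    p$H_ew, rigid_transform(p$H_cg$R, p$H_cg$p + c(1, 0, 0) / sqrt(1), tol = 1e-6))
  sol <- handeye_solve(samples[-4])
  res <- handeye_residuals(samples, sol)
  expect_lt(abs(res$translation_mm[4] - 1), 0.05)
  expect_lt(res$rotation_rad[4], 1e-8)
})

test_that("recovered errors scale about linearly with noise over a decade", {
  tr <- make_truth()
  err_at <- function(sd_rot, sd_tr) {
    samples <- gen_handeye_set(tr$X, tr$G, n = 20,
                               noise_rot_sd = sd_rot, noise_trans_sd = sd_tr,
                               seed = 7)
    sol <- handeye_solve(samples)
    c(rot = rotation_distance(sol$H_ce$R, tr$X$R),
      tr = sqrt(sum((sol$H_ce$p - tr$X$p)^2)))
  }
  lo <- err_at(0.1 * pi / 180, 0.1)
  hi <- err_at(1.0 * pi / 180, 1.0)
  ratio_rot <- hi["rot"] / lo["rot"]
  ratio_tr <- hi["tr"] / lo["tr"]
  expect_gt(ratio_rot, 3); expect_lt(ratio_rot, 30)
  expect_gt(ratio_tr, 3); expect_lt(ratio_tr, 30)
})

test_that("re-expressing the base frame changes H_gw but not H_ce", {
  tr <- make_truth()
  samples <- gen_handeye_set(tr$X, tr$G, n = 10, seed = 8)
  set.seed(81)
  Tb <- random_rt()
  moved <- lapply(samples, function(s) {
    handeye_sample(rt_compose(Tb, s$H_ew), s$H_cg)
  })
  s1 <- handeye_solve(samples)
  s2 <- handeye_solve(moved)
  expect_rt_equal(s1$H_ce, s2$H_ce, tol = 1e-7)
  expect_rt_equal(s2$H_gw, rt_compose(Tb, s1$H_gw), tol = 1e-6)
})

test_that("tidy and glance summarize the solution", {
  tr <- make_truth()
  sol <- handeye_solve(gen_handeye_set(tr$X, tr$G, n = 6, seed = 9))
  td <- tidy(sol)
  expect_equal(nrow(td), 6)
  gl <- glance(sol)
  expect_equal(gl$n_samples, 6)
  expect_lt(gl$max_translation_residual_mm, 1e-8)
})
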