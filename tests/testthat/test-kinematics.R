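test_that("dh_transform reproduces canonical special cases", {
  expect_rt_equal(dh_transform(dh_link(), 0), rt_identity(), tol = 1e-15)
  T1 <- dh_transform(dh_link(a = 100), 0)
  expect_lt(max(abs(T1$p - c(100, 0, 0))), 1e-12)
  expect_lt(max_mat_diff(T1$R, diag(3)), 1e-12)
  # pure offset
  T2 <- dh_transform(dh_link(d = 50), 0)
  expect_lt(max(abs(T2$p - c(0, 0, 50))), 1e-12)
})

test_that("dh_transform matches the element-wise symbolic oracle", {
  set.seed(41)
  for (i in 1:100) {
    a <- stats::runif(1, 0, 200); al <- stats::runif(1, -pi, pi)
    d <- stats::runif(1, -100, 100); th <- stats::runif(1, -pi, pi)
    T1 <- dh_transform(dh_link(a = a, alpha = al, d = d), th)
    M <- rbind(
      c(cos(th), -sin(th) * cos(al), sin(th) * sin(al), a * cos(th)),
      c(sin(th), cos(th) * cos(al), -cos(th) * sin(al), a * sin(th)),
      c(0, sin(al), cos(al), d),
      c(0, 0, 0, 1))
    expect_lt(max_mat_diff(rt_as_matrix(T1), M), 1e-12)
    expect_lt(max_mat_diff(crossprod(T1$R), diag(3)), 1e-12)
    expect_lt(abs(det(T1$R) - 1), 1e-12)
  }
})

test_that("FK of the zero chain is the base pose", {
  ch <- dh_chain(lapply(1:6, function(i) dh_link()),
                 base = rigid_transform(diag(3), c(1, 2, 3)))
  expect_rt_equal(forward_kinematics(ch, rep(0, 6)), ch$base, tol = 1e-12)
})

test_that("planar 2R FK matches hand trigonometry", {
  ch <- dh_chain(list(dh_link(a = 100), dh_link(a = 100)))
  T1 <- forward_kinematics(ch, c(pi / 2, -pi / 2))
  expect_lt(max(abs(T1$p - c(100, 100, 0))), 1e-9)
  T2 <- forward_kinematics(ch, c(0, 0))
  expect_lt(max(abs(T2$p - c(200, 0, 0))), 1e-12)
})

test_that("FK equals the sequential compose oracle on random chains", {
  set.seed(42)
  for (i in 1:100) {
    ch <- random_chain(6)
    q <- stats::runif(6, -pi, pi)
    oracle <- ch$base
    for (j in 1:6) oracle <- rt_compose(oracle, dh_transform(ch$links[[j]], q[j]))
    expect_rt_equal(forward_kinematics(ch, q), oracle, tol = 1e-12)
    # batch evaluator agrees
    P <- woundpath:::fk_positions_batch(ch, matrix(q, 1))
    expect_lt(max(abs(P[1, ] - oracle$p)), 1e-9)
  }
})

test_that("jacobian matches the analytic 2R form and finite differences", {
  ch <- dh_chain(list(dh_link(a = 80), dh_link(a = 50)))
  q <- c(0.3, 0.7)
  J <- jacobian(ch, q)
  # analytic planar 2R Jacobian
  s1 <- sin(q[1]); c1 <- cos(q[1]); s12 <- sin(sum(q)); c12 <- cos(sum(q))
  Ja <- rbind(c(-80 * s1 - 50 * s12, -50 * s12),
              c(80 * c1 + 50 * c12, 50 * c12))
  expect_lt(max(abs(J[1:2, ] - Ja)), 1e-9)

  set.seed(43)
  ch6 <- random_chain(6)
  q6 <- stats::runif(6, -1, 1)
  J6 <- jacobian(ch6, q6)
  h <- 1e-6
  for (i in 1:6) {
    qp <- q6; qm <- q6; qp[i] <- qp[i] + h; qm[i] <- qm[i] - h
    Tp <- forward_kinematics(ch6, qp); Tm <- forward_kinematics(ch6, qm)
    num <- c((Tp$p - Tm$p) / (2 * h),
             woundpath:::rotation_log(Tp$R %*% t(Tm$R)) / (2 * h))
    expect_lt(max(abs(J6[, i] - num)), 1e-5)
  }
})

test_that("a stretched-out pose is rank deficient", {
  ch <- dh_chain(list(dh_link(a = 80), dh_link(a = 50)))
  J <- jacobian(ch, c(0.4, 0))[1:2, ]
  expect_lt(abs(det(J)), 1e-9 * 80 * 50)
})

test_that("IK returns the seed when already at the target", {
  set.seed(44)
  ch <- default_chain()
  q <- stats::runif(6, -1, 1)
  tgt <- forward_kinematics(ch, q)
  sol <- inverse_kinematics(ch, tgt, seed_q = q)
  expect_equal(sol$iterations, 1)
  expect_lt(max(abs(sol$q - q)), 1e-12)
})

test_that("IK round-trips perturbed seeds below 1e-6 mm", {
  set.seed(45)
  ch <- default_chain()
  for (i in 1:20) {
    q <- stats::runif(6, -1, 1)
    tgt <- forward_kinematics(ch, q)
    sol <- inverse_kinematics(ch, tgt, seed_q = q + 0.1)
    fk <- forward_kinematics(ch, sol$q)
    expect_lt(sqrt(sum((fk$p - tgt$p)^2)), 1e-6)
    expect_lt(rotation_distance(fk$R, tgt$R), 1e-6)
  }
})

test_that("targets beyond maximum reach raise an unreachable-pose error", {
  ch <- default_chain()
  expect_error(
    inverse_kinematics(ch, rigid_transform(diag(3), c(5000, 0, 0))),
    "unreachable")
})

test_that("chain YAML round-trips", {
  ch <- default_chain()
  f <- tempfile(fileext = ".yaml")
  write_chain_yaml(ch, f)
  back <- read_chain_yaml(f)
  expect_equal(length(back$links), 6)
  q <- c(0.2, -0.4, 0.6, 0.1, -0.2, 0.5)
  expect_rt_equal(forward_kinematics(back, q), forward_kinematics(ch, q),
                  tol = 1e-9)
})
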