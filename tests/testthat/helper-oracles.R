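# shared test helpers: random rigid transforms and small independent oracles

random_rt <- function(tmax = 100) {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
                2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
                2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
              3, 3)
  rigid_transform(R, stats::runif(3, -tmax, tmax))
}

# independent 4x4 homogeneous multiplication oracle
compose_oracle <- function(a, b) rt_as_matrix(a) %*% rt_as_matrix(b)

max_mat_diff <- function(a, b) max(abs(a - b))

# random revolute chain with n links
random_chain <- function(n = 6) {
  dh_chain(lapply(seq_len(n), function(i) {
    dh_link(a = stats::runif(1, 0, 150), alpha = stats::runif(1, -pi, pi),
            d = stats::runif(1, -50, 50), theta0 = stats::runif(1, -pi, pi),
            limits = c(-pi, pi))
  }))
}

expect_rt_equal <- function(a, b, tol = 1e-9) {
  expect_lt(max_mat_diff(rt_as_matrix(a), rt_as_matrix(b)), tol)
}
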