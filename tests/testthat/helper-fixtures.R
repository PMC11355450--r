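# Shared helpers: seeded random group elements and covectors, and a tiny
# matrix-representation oracle independent of the package's group code.

random_configs <- function(n, seed = 1, sigma_lim = 3) {
  set.seed(seed)
  sim2(runif(n, -2, 2), runif(n, -2, 2), runif(n, -pi, pi),
       runif(n, -sigma_lim, sigma_lim))
}

random_unit_covectors <- function(n, seed = 1, h2_sd = 0.7) {
  set.seed(seed)
  v <- matrix(rnorm(3 * n), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  covector(v[, 1], rnorm(n, sd = h2_sd), v[, 2], v[, 3])
}

# independent oracle: the 3x3 homogeneous similarity matrix built by hand
oracle_matrix <- function(x, y, theta, sigma) {
  es <- exp(sigma)
  rbind(c(es * cos(theta), -es * sin(theta), x),
        c(es * sin(theta), es * cos(theta), y),
        c(0, 0, 1))
}

oracle_unmatrix <- function(m) {
  c(x = m[1, 3], y = m[2, 3],
    theta = atan2(m[2, 1], m[1, 1]),
    sigma = log(sqrt(m[1, 1]^2 + m[2, 1]^2)))
}

expect_config_equal <- function(q, x, y, theta, sigma, tol = 1e-12) {
  expect_equal(unname(q$x), unname(x), tolerance = tol)
  expect_equal(unname(q$y), unname(y), tolerance = tol)
  expect_equal(unname(wrap_angle(q$theta - theta)), 0, tolerance = tol)
  expect_equal(unname(q$sigma), unname(sigma), tolerance = tol)
}
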