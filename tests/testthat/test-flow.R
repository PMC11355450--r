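test_that("Pontryagin pairing is linear and maximized along the momentum", {
  expect_equal(pontryagin_value(covector(1, 0, 0, 0), 1, 0, 0), 1)
  expect_equal(pontryagin_value(covector(0, 0, 1, 0), 0, 1, 0), 1)
  # Cauchy-Schwarz: the maximizing unit control gives value |(h1,h3,h4)|
  for (cs in list(c(1, 0), c(0.6, 0.8), c(-0.3, sqrt(1 - 0.09)))) {
    h <- covector(0.6, 0.37, 0.8 * cs[1], 0.8 * cs[2])
    n <- sqrt(h$h1^2 + h$h3^2 + h$h4^2)
    u <- c(h$h1, h$h3, h$h4) / n
    expect_equal(pontryagin_value(h, u[1], u[2], u[3]), 1, tolerance = 1e-12)
  }
})

test_that("normal flow right-hand side matches the Hamiltonian equations", {
  # purely vertical momentum: fiber motion, frozen momenta
  d <- normal_rhs(sim2_identity(), covector(0, 0, 0.6, 0.8))
  expect_equal(unname(d), c(0, 0, 0.6, 0.8, 0, 0, 0, 0))
  # in-plane momentum decays the scale momentum
  d2 <- normal_rhs(sim2_identity(), covector(1, 0, 0, 0))
  expect_equal(unname(d2), c(1, 0, 0, 0, 0, 0, 0, -1))
  # dH/dt = 2(h1 h1dot + h3 h3dot + h4 h4dot) vanishes identically
  hs <- random_unit_covectors(20, seed = 5)
  qs <- random_configs(20, seed = 6)
  for (i in seq_len(20)) {
    d <- normal_rhs(qs[i, ], hs[i, ])
    dH <- 2 * (hs$h1[i] * d["dh1"] + hs$h3[i] * d["dh3"] +
               hs$h4[i] * d["dh4"])
    expect_lt(abs(dH), 1e-14)
  }
  # pure-R right-hand side agrees with the compiled integrator over a step
  h0 <- covector(0.48, -0.31, 0.6, 0.64074951)
  h0 <- covector(h0$h1 / sqrt(h0$h1^2 + h0$h3^2 + h0$h4^2), h0$h2,
                 h0$h3 / sqrt(h0$h1^2 + h0$h3^2 + h0$h4^2),
                 h0$h4 / sqrt(h0$h1^2 + h0$h3^2 + h0$h4^2))
  tr <- exponential_map(h0, 1e-4, n_samples = 2, renormalize = TRUE)
  d <- normal_rhs(sim2_identity(), attr(tr, "h0"))
  got <- as.numeric(tr[2, c("x", "y", "theta", "sigma",
                            "h1", "h2", "h3", "h4")])
  start <- c(0, 0, 0, 0, unlist(attr(tr, "h0")))
  expect_equal(got, unname(start + 1e-4 * d), tolerance = 1e-7)
})

test_that("exponential map honors the unit level set precondition", {
  expect_error(exponential_map(covector(1, 0, 1, 0), 1), "level set")
  tr <- exponential_map(covector(1, 0, 1, 0), 1, renormalize = TRUE)
  expect_equal(hamiltonian_level(attr(tr, "h0")), 1, tolerance = 1e-12)
})

test_that("pure rotation extremal is 2*pi periodic", {
  fr <- first_return_time(covector(h3 = 1), t_max = 8)
  expect_equal(fr$time, 2 * pi, tolerance = 1e-6)
  # trajectory sanity: theta advances linearly, spatial part frozen
  tr <- exponential_map(covector(h3 = 1), 2 * pi, n_samples = 21)
  expect_lt(max(abs(tr$x), abs(tr$y), abs(tr$sigma)), 1e-10)
  expect_equal(tr$theta, tr$t, tolerance = 1e-9)
})

test_that("fiber extremal follows the closed form and h4 decays off it", {
  tr <- exponential_map(covector(0, 0, 0.6, 0.8), 5, n_samples = 41)
  expect_lt(max(abs(tr$x), abs(tr$y)), 1e-12)
  expect_equal(tr$theta, 0.6 * tr$t, tolerance = 1e-10)
  expect_equal(tr$sigma, 0.8 * tr$t, tolerance = 1e-10)
  # h4 non-increasing along any extremal (h4dot = -h1^2)
  tr2 <- exponential_map(covector(1, 0, 0, 0), 10, n_samples = 201)
  expect_true(all(diff(tr2$h4) <= 1e-12))
})

test_that("trajectories are horizontal, unit speed, and conserve integrals", {
  hs <- random_unit_covectors(25, seed = 42)
  for (i in seq_len(25)) {
    tr <- exponential_map(hs[i, ], 10, n_samples = 51)
    # conservation (relative drift)
    g <- glance(tr)
    expect_lt(g$H_drift, 1e-8)
    expect_lt(g$g1_drift, 1e-8)
    expect_lt(g$g2_drift, 1e-8)
    # unit speed in the extremal controls
    expect_lt(max(abs(horizontal_speed(tr$u1, tr$u3, tr$u4) - 1)), 1e-6)
    # horizontality: the chart velocity annihilates the contact form
    for (k in c(1, 26, 51)) {
      q <- sim2(tr$x[k], tr$y[k], tr$theta[k], tr$sigma[k])
      v <- normal_rhs(q, covector(tr$h1[k], tr$h2[k], tr$h3[k], tr$h4[k]))
      expect_lt(abs(contact_pairing(q, v[1:4])), 1e-6)
    }
  }
})

test_that("extremals started off the identity are left translates", {
  hs <- random_unit_covectors(8, seed = 77)
  qs <- random_configs(8, seed = 78, sigma_lim = 1)
  for (i in seq_len(8)) {
    tr0 <- exponential_map(hs[i, ], 3, n_samples = 11)
    trq <- exponential_map(hs[i, ], 3, n_samples = 11, q0 = qs[i, ])
    moved <- sim2_multiply(qs[i, ], sim2(tr0$x, tr0$y, tr0$theta, tr0$sigma))
    expect_lt(max(endpoint_error(moved,
                                 sim2(trq$x, trq$y, trq$theta, trq$sigma))),
              1e-8)
    # vertical dynamics identical regardless of base point
    expect_equal(trq$h1, tr0$h1, tolerance = 1e-8)
    expect_equal(trq$h4, tr0$h4, tolerance = 1e-8)
  }
})

test_that("abnormal trajectories are vertical scale lines matching the flow", {
  a <- abnormal_trajectory(1, direction = 1, n_samples = 5)
  expect_config_equal(sim2(a$x[5], a$y[5], a$theta[5], a$sigma[5]), 0, 0, 0, 1)
  a0 <- abnormal_trajectory(0, n_samples = 2)
  expect_config_equal(sim2(a0$x[2], a0$y[2], a0$theta[2], a0$sigma[2]),
                      0, 0, 0, 0)
  # not strictly abnormal: coincides with the normal extremal h0=(0,0,0,-1)
  am <- abnormal_trajectory(2, direction = -1, n_samples = 21)
  nm <- exponential_map(covector(0, 0, 0, -1), 2, n_samples = 21)
  expect_lt(max(abs(am$x - nm$x), abs(am$y - nm$y),
                abs(am$theta - nm$theta), abs(am$sigma - nm$sigma)), 1e-9)
})

test_that("fiber geodesics carry the cut time pi/|h30|", {
  f <- fiber_geodesic(0.6, 0.8, 2)
  expect_equal(cut_time(f), pi / 0.6)
  expect_equal(cut_time(fiber_geodesic(0, 1, 2)), Inf)
  f2 <- fiber_geodesic(1, 0, pi / 2, n_samples = 3)
  expect_config_equal(sim2(f2$x[3], f2$y[3], f2$theta[3], f2$sigma[3]),
                      0, 0, pi / 2, 0)
  # closed form agrees with the integrated flow in sup norm
  tint <- exponential_map(covector(0, 0, 0.6, 0.8), 5, n_samples = 101)
  tcf <- fiber_geodesic(0.6, 0.8, 5, n_samples = 101)
  expect_lt(max(abs(tint$x - tcf$x), abs(tint$y - tcf$y),
                abs(tint$theta - tcf$theta), abs(tint$sigma - tcf$sigma)),
            1e-9)
})

test_that("mirror fiber geodesics meet at the Maxwell point", {
  mp <- maxwell_pair(0.6, 0.8)
  expect_equal(mp$time, pi / 0.6, tolerance = 1e-6)
  expect_equal(mp$theta_abs, pi, tolerance = 1e-6)
  expect_equal(mp$config$sigma, (0.8 / 0.6) * pi, tolerance = 1e-6)
  expect_lt(mp$coincidence_error, 1e-6)
  mp2 <- maxwell_pair(1, 0)
  expect_equal(mp2$time, pi, tolerance = 1e-6)
  expect_config_equal(mp2$config, 0, 0, pi, 0, tol = 1e-6)
  expect_error(maxwell_pair(0, 1), "no Maxwell")
})

test_that("first integrals take their closed forms at the identity", {
  h <- covector(0.3, -0.2, 0.8, 0.52)
  fi <- first_integrals(sim2_identity(), h)
  expect_equal(fi$g1, 0.3)
  expect_equal(fi$g2, -0.2)
  hu <- random_unit_covectors(5, seed = 3)
  expect_equal(first_integrals(sim2_identity(), hu)$H, rep(1, 5),
               tolerance = 1e-12)
})

test_that("frame and chart momenta are mutually inverse linear maps", {
  # at the identity the two coordinate systems coincide
  h <- covector(0.1, 0.2, 0.3, 0.4)
  p <- chart_momentum(h, sim2_identity())
  expect_equal(as.numeric(p), c(0.1, 0.2, 0.3, 0.4))
  # a quarter turn exchanges the in-plane momenta (with the sign fixed by
  # the pairing against X2 = e^sigma(-sin, cos))
  h2 <- frame_momentum(tibble::tibble(p1 = 1, p2 = 0, p3 = 0, p4 = 0),
                       sim2(0, 0, pi / 2, 0))
  expect_equal(as.numeric(h2), c(0, -1, 0, 0), tolerance = 1e-12)
  # round trip at random configurations
  qs <- random_configs(30, seed = 51)
  hs <- random_unit_covectors(30, seed = 52)
  back <- frame_momentum(chart_momentum(hs, qs), qs)
  expect_lt(max(abs(as.matrix(back) - as.matrix(hs))), 1e-12)
  # p3, p4 always pass through
  expect_equal(chart_momentum(hs, qs)$p3, hs$h3)
  expect_equal(chart_momentum(hs, qs)$p4, hs$h4)
  # the conserved g1, g2 are exactly the constant chart momenta
  tr <- exponential_map(covector(0.6, 0.1, 0.64, 0.48), 4, n_samples = 9,
                        renormalize = TRUE)
  p_along <- chart_momentum(tr[, c("h1", "h2", "h3", "h4")],
                            tr[, c("x", "y", "theta", "sigma")])
  expect_lt(max(abs(p_along$p1 - p_along$p1[1])), 1e-9)
  expect_lt(max(abs(p_along$p2 - p_along$p2[1])), 1e-9)
})

test_that("Poisson bivector has rank 4 iff the in-plane momenta are nonzero", {
  p <- poisson_matrix(covector(1, 1, 0.5, 0.3))
  expect_equal(p$rank, 4)
  expect_true(all(p$P == -t(p$P)))
  expect_equal(p$det, (1^2 + 1^2)^2)
  expect_equal(poisson_matrix(covector(0, 0, 1, 0))$rank, 0)
  expect_equal(poisson_matrix(covector(1, 0, 0.2, -2))$det, 1)
  hs <- random_unit_covectors(10, seed = 91)
  for (i in seq_len(10)) {
    p <- poisson_matrix(hs[i, ])
    expect_equal(p$det, (hs$h1[i]^2 + hs$h2[i]^2)^2, tolerance = 1e-12)
  }
})

test_that("vertical subsystem decays to the h3-h4 circle when h4(0) < 0", {
  vt <- vertical_tail(covector(0.6, 0, 0, -0.8), 50)
  expect_lt(vt$abs_h1, 1e-6)
  expect_lt(vt$abs_h2, 1e-6)
  expect_equal(vt$h3sq_plus_h4sq, 1, tolerance = 1e-6)
  expect_true(vt$h4_nonincreasing)
  # degenerate orbit: purely vertical momenta stay frozen
  vt2 <- vertical_tail(covector(0, 0, 0.6, 0.8), 20)
  expect_equal(as.numeric(vt2$h_tail), c(0, 0, 0.6, 0.8), tolerance = 1e-9)
  # conjectured regime h4(0) >= 0: reported, not asserted as a theorem
  vt3 <- vertical_tail(covector(1, 0, 0, 0), 50)
  expect_lt(vt3$abs_h1, 1e-3)
  expect_lt(vt3$h_tail$h4, 0)
})

test_that("spatial projection stabilizes for decaying extremals", {
  hs <- random_unit_covectors(5, seed = 101)
  hs$h4 <- -abs(hs$h4)
  n <- sqrt(hs$h1^2 + hs$h3^2 + hs$h4^2)
  hs <- covector(hs$h1 / n, hs$h2, hs$h3 / n, hs$h4 / n)
  for (i in seq_len(5)) {
    tr <- exponential_map(hs[i, ], 50, n_samples = 501)
    r <- sqrt(tr$x^2 + tr$y^2)
    expect_true(all(is.finite(r)))
    tail_inc <- max(abs(diff(r[tr$t > 40])))
    expect_lt(tail_inc, 1e-6)
  }
})
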