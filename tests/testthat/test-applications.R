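test_that("association field is mirror symmetric and spatially bounded", {
  af <- association_field(t_max = 20, n_per_curve = 120)
  expect_equal(length(unique(af$curve_id)), 10)
  # the straight rays (h30 = 0) stay on the x axis
  ray <- dplyr::filter(af, .data$h30 == 0, .data$h10 > 0)
  expect_lt(max(abs(ray$y)), 1e-10)
  expect_lt(max(abs(ray$theta)), 1e-10)
  # y -> -y symmetry pairs +-h30
  for (pair in list(c(3, 4), c(5, 6), c(7, 8), c(9, 10))) {
    a <- dplyr::filter(af, .data$curve_id == pair[1])
    b <- dplyr::filter(af, .data$curve_id == pair[2])
    expect_lt(max(abs(a$x - b$x)), 1e-8)
    expect_lt(max(abs(a$y + b$y)), 1e-8)
  }
  # bounded spatial propagation at the horizon
  expect_lt(max(sqrt(af$x^2 + af$y^2)), 5)
})

test_that("grouping scene meets its spacing and separation contracts", {
  sc <- build_grouping_scene(seed = 42)
  fg <- sc$foreground
  for (g in split(fg, fg$curve_id))
    expect_lt(max(abs(diff(g$t) - 0.1)), 1e-3)
  bg <- sc$background
  expect_true(all(bg$sigma >= 0 & bg$sigma <= 1.8))
  n <- nrow(bg)
  pairs <- utils::combn(n, 2)
  lbs <- sr_distance_lower_bound(
    sim2(bg$x[pairs[1, ]], bg$y[pairs[1, ]], bg$theta[pairs[1, ]],
         bg$sigma[pairs[1, ]]),
    sim2(bg$x[pairs[2, ]], bg$y[pairs[2, ]], bg$theta[pairs[2, ]],
         bg$sigma[pairs[2, ]]))
  expect_gt(min(lbs), 0.18)
  # consecutive foreground spacing is a true sub-Riemannian distance for a
  # few spot-checked minimizing sub-arcs
  g1 <- fg[fg$curve_id == 1, ]
  d <- sr_distance(sim2(g1$x[1], g1$y[1], g1$theta[1], g1$sigma[1]),
                   sim2(g1$x[2], g1$y[2], g1$theta[2], g1$sigma[2]))
  expect_equal(d, 0.1, tolerance = 1e-3)
})

test_that("grouping scenes are deterministic and reject infeasible configs", {
  s1 <- build_grouping_scene(seed = 7)
  s2 <- build_grouping_scene(seed = 7)
  expect_identical(s1$foreground, s2$foreground)
  expect_identical(s1$background, s2$background)
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_scene_json(s1, f1); write_scene_json(s2, f2)
  expect_identical(readLines(f1), readLines(f2))
  s3 <- build_grouping_scene(seed = 8)
  expect_false(identical(s1$background, s3$background))
  expect_error(build_grouping_scene(spacing_d = 0.2), "infeasible")
  expect_error(build_grouping_scene(grid_n = 40), "infeasible")
})

test_that("trajectory rendering stamps thickness-scaled footprints", {
  canvas <- image_grid(matrix(0, 41, 41))
  # fiber geodesic: spatial projection is a point; footprint one disc
  f <- fiber_geodesic(0.6, 0.8, 1.5, n_samples = 60)
  out <- render_trajectory(f, canvas)
  hit <- which(out$intensities > 0, arr.ind = TRUE)
  expect_gt(nrow(hit), 0)
  rad <- max(sqrt((hit[, 1] - 21)^2 + (hit[, 2] - 21)^2))
  expect_lte(rad, exp(max(f$sigma)) / 2 + 1)
  # abnormal trajectory: same single-point footprint
  ab <- render_trajectory(abnormal_trajectory(1, 1, 30), canvas)
  hit2 <- which(ab$intensities > 0, arr.ind = TRUE)
  expect_lte(max(sqrt((hit2[, 1] - 21)^2 + (hit2[, 2] - 21)^2)),
             exp(1) / 2 + 1)
  # straight ray: start from a thick configuration so the stroke spans
  # several pixels before the in-plane momentum decays
  tr <- exponential_map(covector(1, 0, 0, 0), 2.2, n_samples = 80,
                        q0 = sim2(-6, 0, 0, log(6)))
  ray <- render_trajectory(tr, canvas)
  row21 <- ray$intensities[21, ]
  covered <- which(row21 > 0)
  expect_gt(length(covered), 5)
  expect_equal(covered, seq(min(covered), max(covered)))  # no gaps
  # re-stamping is idempotent
  again <- render_trajectory(tr, ray)
  expect_equal(again$intensities, ray$intensities)
})

test_that("completion restores a severed bar and leaves the rest untouched", {
  bank <- calibrate_bank(gabor_bank(sigma_grid = seq(-0.5, 2.8,
                                                     length.out = 12)))
  fx <- make_curve_image(cbind(c(-30, 30), c(0, 0)), widths = 12,
                         nx = 61, ny = 61)
  cor <- corrupt_with_disc(fx$image, c(0, 0), 7)
  res <- complete_contours(cor$image, cor$mask, bank)
  expect_gte(binary_iou(res, fx$image, region = cor$mask), 0.9)
  expect_identical(res$intensities[!cor$mask],
                   cor$image$intensities[!cor$mask])
  pairs <- attr(res, "pairs")
  expect_equal(nrow(pairs), 1)
  expect_lt(pairs$residual, 1e-6)
  # empty mask: nothing to restore
  res0 <- complete_contours(fx$image, matrix(FALSE, 61, 61), bank)
  expect_identical(res0$intensities, fx$image$intensities)
})

test_that("thickness interpolates across a tapered gap", {
  # geodesic level: when the scale change dominates the spatial gap
  # (x^2 <= e^{2 dsigma} - 1 in relative coordinates) the connecting
  # geodesic's sigma is monotone
  s <- shoot(sim2(2.5, 0, 0, log(3)))
  expect_true(s$converged)
  dsg <- diff(s$trajectory$sigma)
  expect_true(all(dsg >= -1e-8))
  # pipeline level: completing a tapered bar interpolates the width with at
  # most a bounded overshoot (travel is cheaper at larger scales, so the
  # minimizer may swell slightly above the thicker endpoint)
  bank <- calibrate_bank(gabor_bank(sigma_grid = seq(-0.5, 3.2,
                                                     length.out = 14)))
  fx <- make_curve_image(cbind(c(-30, 30), c(0, 0)), widths = c(6, 18),
                         nx = 61, ny = 61)
  grid <- fx$image
  cc <- sim2geo:::pixel_xy(grid, outer(seq_len(61), rep(1, 61)),
                           outer(rep(1, 61), seq_len(61)))
  mask <- abs(cc$x) <= 4
  corrupted <- grid$intensities; corrupted[mask] <- 0
  res <- complete_contours(image_grid(corrupted), mask, bank)
  pairs <- attr(res, "pairs")
  expect_equal(nrow(pairs), 1)
  ep <- attr(res, "endpoints")
  qa <- sim2(ep$x[which.min(ep$x)], ep$y[which.min(ep$x)],
             ep$theta[which.min(ep$x)], ep$sigma_phys[which.min(ep$x)])
  qb <- sim2(ep$x[which.max(ep$x)], ep$y[which.max(ep$x)],
             ep$theta[which.max(ep$x)] + pi, ep$sigma_phys[which.max(ep$x)])
  st <- shoot(sim2_multiply(sim2_inverse(qa), qb))
  expect_true(st$converged)
  sg <- st$trajectory$sigma + qa$sigma
  # net thickening from the thin to the thick side, no dip below the thin
  # width, bounded overshoot above the thick width
  expect_gt(sg[length(sg)], sg[1] + 0.5)
  expect_gt(min(sg), sg[1] - 1e-6)
  expect_lt(max(sg), max(sg[1], sg[length(sg)]) + log(2))
})
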