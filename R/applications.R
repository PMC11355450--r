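#' Association field from a fan of geodesics
#'
#' Integrates the exponential map for the ten canonical initial covectors
#' with `h2(0) = h4(0) = 0` and
#' `(h1(0), h3(0))` in `{(+-1, 0), (+-0.93, +-0.35), (+-0.99, +-0.11)}`
#' (each pair renormalized onto the unit level set, which the two-decimal
#' values miss slightly) and returns the planar projections.  The family is
#' symmetric under `y -> -y` (pairing `+-h3`), and its spatial extent stays
#' bounded as the horizon grows: the in-plane momentum decays, so the
#' geodesics stop propagating spatially — the model's analogue of the finite
#' reach of perceptual contour association.
#'
#' @param t_max Integration horizon (arc length).
#' @param n_per_curve Samples per curve.
#' @return A tibble with `curve_id`, the generating `h10`, `h30`, and the
#'   sampled `t`, `x`, `y`, `theta`, `sigma`.
#' @export
association_field <- function(t_max = 20, n_per_curve = 400) {
  h13 <- rbind(c(1, 0), c(-1, 0),
               c(0.93, 0.35), c(0.93, -0.35), c(-0.93, 0.35), c(-0.93, -0.35),
               c(0.99, 0.11), c(0.99, -0.11), c(-0.99, 0.11), c(-0.99, -0.11))
  purrr::map_dfr(seq_len(nrow(h13)), function(k) {
    h0 <- covector(h13[k, 1], 0, h13[k, 2], 0)
    tr <- exponential_map(h0, t_max, n_samples = n_per_curve,
                          renormalize = TRUE)
    tibble::tibble(curve_id = k, h10 = h13[k, 1], h30 = h13[k, 2],
                   t = tr$t, x = tr$x, y = tr$y,
                   theta = tr$theta, sigma = tr$sigma)
  })
}

# sample a seeded unit covector with h4 < 0 (decaying spatial propagation)
random_unit_covector <- function(h2_sd = 0.3) {
  v <- stats::rnorm(3)
  v <- v / sqrt(sum(v^2))
  covector(v[1], stats::rnorm(1, sd = h2_sd), v[2], -abs(v[3]))
}

#' Build a perceptual-grouping scene
#'
#' Constructs the grouping demonstration: foreground elements placed
#' equidistantly (sub-Riemannian spacing `spacing_d`, the default 0.1) along
#' three geodesic segments, drawn over a background of elements on a regular
#' spatial grid whose orientations are random on the circle and log-scales
#' random in `sigma_range`, resampled until every background pair is
#' certifiably separated by more than `min_bg_separation` (default 0.18) in
#' the sub-Riemannian distance — certified through the orientation/scale
#' lower bound, which spatial position cannot reduce.  Unit-speed
#' parameterization makes arc-length steps along a minimizing segment equal
#' sub-Riemannian distances, so foreground spacing holds by construction.
#'
#' @param spacing_d Along-curve spacing of foreground elements.
#' @param min_bg_separation Certified lower bound on background pair
#'   distances; must exceed `spacing_d`.
#' @param sigma_range Interval for background log-scales.
#' @param grid_n Background grid is `grid_n x grid_n`.
#' @param segment_length Arc length of each foreground geodesic segment.
#' @param n_segments Number of foreground segments.
#' @param seed Integer seed; the same seed reproduces the scene exactly.
#' @param max_tries Rejection-sampling budget per background element.
#' @return An object of class `grouping_scene`: list with `foreground` and
#'   `background` tibbles and the generating parameters.
#' @export
build_grouping_scene <- function(spacing_d = 0.1, min_bg_separation = 0.18,
                                 sigma_range = c(0, 1.8), grid_n = 6,
                                 segment_length = 1, n_segments = 3,
                                 seed = 42, max_tries = 400) {
  if (spacing_d <= 0 || min_bg_separation <= spacing_d)
    stop("infeasible configuration: need 0 < spacing_d < min_bg_separation",
         call. = FALSE)
  if (diff(sigma_range) <= 0) stop("sigma_range must be increasing",
                                   call. = FALSE)
  # capacity of the (theta, sigma) torus strip under L-infinity packing
  capacity <- floor(2 * pi / min_bg_separation) *
    floor(diff(sigma_range) / min_bg_separation + 1)
  if (grid_n^2 > capacity)
    stop("infeasible configuration: ", grid_n^2, " background elements ",
         "cannot be packed with separation ", min_bg_separation, call. = FALSE)

  old <- .Random.seed2_save()
  on.exit(.Random.seed2_restore(old), add = TRUE)
  set.seed(seed)

  fg <- purrr::map_dfr(seq_len(n_segments), function(k) {
    h0 <- random_unit_covector()
    anchor <- sim2(stats::runif(1, -1.5, 1.5), stats::runif(1, -1.5, 1.5),
                   stats::runif(1, -pi, pi), stats::runif(1, 0.2, 0.9))
    ts <- seq(0, segment_length, by = spacing_d)
    tr <- exponential_map(h0, segment_length, n_samples = 2001, q0 = anchor)
    idx <- vapply(ts, function(t) which.min(abs(tr$t - t)), integer(1))
    tibble::tibble(curve_id = k, t = tr$t[idx], x = tr$x[idx], y = tr$y[idx],
                   theta = tr$theta[idx], sigma = tr$sigma[idx],
                   h10 = h0$h1, h20 = h0$h2, h30 = h0$h3, h40 = h0$h4)
  })

  ext <- range(c(fg$x, fg$y))
  pad <- 0.35 * diff(ext) + 0.5
  centers <- seq(ext[1] - pad, ext[2] + pad, length.out = grid_n)
  bg_xy <- expand.grid(x = centers, y = centers)
  th <- numeric(0); sg <- numeric(0)
  for (i in seq_len(nrow(bg_xy))) {
    ok <- FALSE
    for (tries in seq_len(max_tries)) {
      cand_th <- stats::runif(1, -pi, pi)
      cand_sg <- stats::runif(1, sigma_range[1], sigma_range[2])
      if (i == 1 ||
          all(pmax(abs(wrap_angle(th - cand_th)), abs(sg - cand_sg)) >
              min_bg_separation)) {
        ok <- TRUE; break
      }
    }
    if (!ok) stop("could not place background element ", i,
                  " with the requested separation", call. = FALSE)
    th <- c(th, cand_th); sg <- c(sg, cand_sg)
  }
  bg <- tibble::tibble(x = bg_xy$x, y = bg_xy$y, theta = th, sigma = sg)

  structure(list(foreground = fg, background = bg,
                 params = list(spacing_d = spacing_d,
                               min_bg_separation = min_bg_separation,
                               sigma_range = sigma_range, grid_n = grid_n,
                               segment_length = segment_length,
                               n_segments = n_segments, seed = seed)),
            class = "grouping_scene")
}

#' @export
print.grouping_scene <- function(x, ...) {
  cat(sprintf(paste0("<grouping_scene> %d foreground elements on %d segments",
                     " (spacing %g), %d background elements (separation > %g)\n"),
              nrow(x$foreground), x$params$n_segments, x$params$spacing_d,
              nrow(x$background), x$params$min_bg_separation))
  invisible(x)
}

#' Rasterize a thick trajectory onto a canvas
#'
#' Stamps discs of diameter `exp(sigma(t) + sigma_offset)` (retinal units)
#' along the planar projection of a trajectory.  Stamping takes the pixelwise
#' maximum with the existing canvas, so re-stamping covered pixels is
#' idempotent.  Samples falling outside the canvas are clipped with a
#' warning.  An optional mask restricts writing to the damaged region, which
#' keeps completion conservative outside it.
#'
#' @param traj An `sr_trajectory` (or tibble with `x`, `y`, `sigma`).
#' @param canvas An [image_grid()].
#' @param intensity Stamp gray level.
#' @param sigma_offset Added to `sigma` before exponentiating; used to map
#'   bank-calibrated log-scales to physical widths.
#' @param mask Optional logical matrix; only `TRUE` pixels may change.
#' @param oversample Resampling factor ensuring consecutive stamps overlap.
#' @return The canvas with the stroke rendered.
#' @export
render_trajectory <- function(traj, canvas, intensity = 1, sigma_offset = 0,
                              mask = NULL, oversample = 4) {
  stopifnot(is.data.frame(traj), nrow(traj) >= 1,
            inherits(canvas, "image_grid"))
  ps <- canvas$pixel_size
  out <- canvas$intensities
  nr <- nrow(out); nc <- ncol(out)
  cc <- pixel_xy(canvas, outer(seq_len(nr), rep(1, nc)),
                 outer(rep(1, nr), seq_len(nc)))
  # resample the polyline finely enough that discs overlap
  n <- nrow(traj)
  if (n > 1) {
    seg <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
    n_out <- max(n, ceiling(oversample * sum(seg) / ps) + 1)
    s <- c(0, cumsum(seg))
    si <- seq(0, max(s), length.out = n_out)
    xs <- stats::approx(s, traj$x, si, ties = "ordered")$y
    ys <- stats::approx(s, traj$y, si, ties = "ordered")$y
    sg <- stats::approx(s, traj$sigma, si, ties = "ordered")$y
  } else {
    xs <- traj$x; ys <- traj$y; sg <- traj$sigma
  }
  clipped <- FALSE
  for (i in seq_along(xs)) {
    rad <- exp(sg[i] + sigma_offset) / 2
    hit <- (cc$x - xs[i])^2 + (cc$y - ys[i])^2 <= rad^2
    if (!any(hit)) {
      p <- xy_pixel(canvas, xs[i], ys[i])
      if (p$row < 1 || p$row > nr || p$col < 1 || p$col > nc) clipped <- TRUE
      next
    }
    if (!is.null(mask)) hit <- hit & mask
    out[hit] <- pmax(out[hit], intensity)
  }
  if (clipped) warning("trajectory extends outside the canvas; clipped")
  image_grid(out, ps, canvas$origin)
}

# orient an extracted boundary configuration so theta points into the mask
orient_into_mask <- function(cfg, img, mask, probe = 2) {
  purrr::map_dfr(seq_len(nrow(cfg)), function(i) {
    row <- cfg$row[i]; col <- cfg$col[i]
    score <- function(th) {
      hits <- 0
      for (step in seq(1, probe * 2)) {
        p <- xy_pixel(img, cfg$x[i] + step * img$pixel_size * cos(th) / 2,
                      cfg$y[i] + step * img$pixel_size * sin(th) / 2)
        if (p$row >= 1 && p$row <= nrow(mask) &&
            p$col >= 1 && p$col <= ncol(mask) && mask[p$row, p$col])
          hits <- hits + 1
      }
      hits
    }
    th0 <- cfg$theta[i]
    th <- if (score(th0) >= score(th0 + pi)) th0 else th0 + pi
    out <- cfg[i, ]
    out$theta <- wrap_angle(th)
    out
  })
}

#' Complete damaged contours with sub-Riemannian geodesics
#'
#' The full inpainting workflow: extract boundary configurations where
#' contours meet the damage mask, resolve the antipodal orientation ambiguity
#' by pointing each endpoint into the mask, pair endpoints greedily by
#' ascending sub-Riemannian distance, connect each pair by a shooting
#' geodesic in SIM(2), and render every connecting geodesic into the masked
#' region as a stroke whose local width follows `exp(sigma(t))` through the
#' bank's width calibration.  Pixels outside the mask are returned
#' bit-identical to the input.
#'
#' @param img An [image_grid()] (or matrix).
#' @param mask Logical damage mask, same shape.
#' @param bank A [gabor_bank()]; calibrated on the fly if needed.
#' @param response_frac Endpoint detection threshold, see
#'   [extract_boundary_configurations()].
#' @param intensity Stroke intensity; default is the maximum intensity at
#'   the detected endpoints.
#' @param ... Passed to [shoot()].
#' @return The restored [image_grid()], with attributes `endpoints`
#'   (oriented boundary configurations), `pairs` (tibble of connected pairs
#'   with distances) and `unmatched` (indices left over when the endpoint
#'   count is odd).
#' @export
complete_contours <- function(img, mask, bank = NULL, response_frac = 0.25,
                              intensity = NULL, ...) {
  if (is.matrix(img)) img <- image_grid(img)
  stopifnot(inherits(img, "image_grid"), is.matrix(mask),
            all(dim(mask) == dim(img$intensities)))
  mask <- mask > 0
  if (!any(mask)) return(img)
  if (is.null(bank))
    bank <- gabor_bank(pixel_size = img$pixel_size,
                       sigma_grid = seq(-0.5, 2.2, length.out = 12))
  if (is.na(bank$calibration)) bank <- calibrate_bank(bank)

  # scale-adaptive probing: filters centered near the cut face see the
  # contour termination, so the probe ring must stand off by about one
  # contour width; iterate offset <- estimated width until stable
  off <- 3
  off_cap <- max(3, floor(min(dim(mask)) / 3))
  ep <- extract_boundary_configurations(img, mask, bank,
                                        response_frac = response_frac,
                                        probe_offset = off)
  for (iter in seq_len(6)) {
    if (nrow(ep) == 0) break
    w_est <- max(exp(ep$sigma - bank$calibration))
    off_new <- min(off_cap, max(3, ceiling(w_est)))
    if (off_new <= off) break
    off <- off_new
    ep <- extract_boundary_configurations(img, mask, bank,
                                          response_frac = response_frac,
                                          probe_offset = off)
  }
  if (nrow(ep) == 0) return(img)
  ep <- orient_into_mask(ep, img, mask)
  # physical log-width in retinal units (drives both geodesic and rendering)
  ep$sigma_phys <- ep$sigma - bank$calibration

  n <- nrow(ep)
  restored <- img
  pairs <- tibble::tibble()
  unmatched <- integer(0)
  if (n < 2) {
    unmatched <- seq_len(n)
  } else {
    # pair endpoints: a's direction points into the mask (travel direction),
    # b's must point out of the mask at exit, i.e. its into-mask angle + pi
    cand <- tidyr::expand_grid(i = seq_len(n), j = seq_len(n)) |>
      dplyr::filter(.data$i < .data$j)
    shots <- vector("list", nrow(cand))
    dist <- rep(Inf, nrow(cand))
    for (k in seq_len(nrow(cand))) {
      a <- ep[cand$i[k], ]; b <- ep[cand$j[k], ]
      qa <- sim2(a$x, a$y, a$theta, a$sigma_phys)
      qb <- sim2(b$x, b$y, b$theta + pi, b$sigma_phys)
      s <- shoot(sim2_multiply(sim2_inverse(qa), qb), ...)
      if (s$converged) { shots[[k]] <- list(s = s, qa = qa); dist[k] <- s$T }
    }
    taken <- rep(FALSE, n)
    for (k in order(dist)) {
      if (!is.finite(dist[k])) break
      i <- cand$i[k]; j <- cand$j[k]
      if (taken[i] || taken[j]) next
      taken[i] <- TRUE; taken[j] <- TRUE
      s <- shots[[k]]$s; qa <- shots[[k]]$qa
      # left-translate the identity-based geodesic to start at qa
      tr <- s$trajectory
      qmoved <- sim2_multiply(qa, sim2(tr$x, tr$y, tr$theta, tr$sigma))
      tr_abs <- tibble::tibble(x = qmoved$x, y = qmoved$y,
                               sigma = qmoved$sigma)
      amp <- if (is.null(intensity))
        max(img$intensities[ep$row[c(i, j)] + (ep$col[c(i, j)] - 1) *
                              nrow(img$intensities)], 1e-3) else intensity
      restored <- render_trajectory(tr_abs, restored, intensity = amp,
                                    mask = mask)
      pairs <- dplyr::bind_rows(pairs, tibble::tibble(
        i = i, j = j, T = s$T, residual = s$residual))
    }
    unmatched <- which(!taken)
  }
  attr(restored, "endpoints") <- ep
  attr(restored, "pairs") <- pairs
  attr(restored, "unmatched") <- unmatched
  restored
}

#' Intersection-over-union of two binary images
#'
#' Compares stroke masks (intensity above `threshold`), optionally only
#' within a region; the completion tests score restored contours against the
#' pre-corruption original inside the damage mask with this.
#'
#' @param a,b [image_grid()]s or matrices of equal shape.
#' @param region Optional logical matrix restricting the comparison.
#' @param threshold Binarization threshold.
#' @return IoU in `[0, 1]` (1 when both masks are empty).
#' @export
binary_iou <- function(a, b, region = NULL, threshold = 0.5) {
  A <- if (inherits(a, "image_grid")) a$intensities else a
  B <- if (inherits(b, "image_grid")) b$intensities else b
  stopifnot(all(dim(A) == dim(B)))
  A <- A > threshold; B <- B > threshold
  if (!is.null(region)) { A <- A & region; B <- B & region }
  u <- sum(A | B)
  if (u == 0) return(1)
  sum(A & B) / u
}
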