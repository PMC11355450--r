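#' Image grids in retinal coordinates
#'
#' Wraps a matrix of nonnegative intensities together with its mapping to
#' retinal-plane coordinates: x grows to the right (columns), y grows upward
#' (rows read bottom-up), origin at the image center by default.
#'
#' @param intensities Numeric matrix, values `>= 0`.
#' @param pixel_size Retinal units per pixel.
#' @param origin Length-2 retinal coordinates of the image center.
#' @return An object of class `image_grid`.
#' @export
image_grid <- function(intensities, pixel_size = 1, origin = c(0, 0)) {
  stopifnot(is.matrix(intensities), all(intensities >= 0),
            pixel_size > 0, length(origin) == 2)
  structure(list(intensities = intensities, pixel_size = pixel_size,
                 origin = as.numeric(origin)),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid> %d x %d pixels, pixel_size = %g, origin = (%g, %g)\n",
              nrow(x$intensities), ncol(x$intensities), x$pixel_size,
              x$origin[1], x$origin[2]))
  invisible(x)
}

# retinal coordinates of pixel centers; row 1 is the top of the image
pixel_xy <- function(grid, row, col) {
  nr <- nrow(grid$intensities); nc <- ncol(grid$intensities)
  list(x = grid$origin[1] + (col - (nc + 1) / 2) * grid$pixel_size,
       y = grid$origin[2] + ((nr + 1) / 2 - row) * grid$pixel_size)
}

# nearest pixel indices for retinal coordinates (may fall outside the canvas)
xy_pixel <- function(grid, x, y) {
  nr <- nrow(grid$intensities); nc <- ncol(grid$intensities)
  list(row = round((nr + 1) / 2 - (y - grid$origin[2]) / grid$pixel_size),
       col = round((x - grid$origin[1]) / grid$pixel_size + (nc + 1) / 2))
}

#' Gabor receptive profile on SIM(2)
#'
#' The mother profile `G(x, y) = exp(-(x^2 + y^2)) cos(2 y)` rotated by
#' `theta` and dilated by `e^sigma`:
#' `G_(theta,sigma)(x, y) = e^{-2 sigma} exp(-(x_t^2 + y_t^2)) cos(2 y_t)`
#' with `x_t = e^{-sigma}( x cos theta + y sin theta)`,
#' `y_t = e^{-sigma}(-x sin theta + y cos theta)`.  The profile is even, so
#' responses are `pi`-periodic in `theta`.  Vectorized over `x`, `y`.
#'
#' @param theta Orientation (radians); @param sigma log-scale.
#' @param x,y Retinal coordinates.
#' @return Numeric profile values.
#' @export
gabor_profile <- function(theta, sigma, x, y) {
  es <- exp(-sigma)
  xt <- es * (x * cos(theta) + y * sin(theta))
  yt <- es * (-x * sin(theta) + y * cos(theta))
  exp(-2 * sigma) * exp(-(xt^2 + yt^2)) * cos(2 * yt)
}

#' Two-parameter Gabor filter bank
#'
#' Precomputes rotated and dilated receptive profiles on the pixel lattice.
#' Orientations sample `[0, pi)` (the even profile cannot distinguish
#' antipodal directions; contour direction is resolved later, during endpoint
#' pairing); log-scales default to a uniform grid on `[-1, 1.8]`.  Kernels
#' are truncated at `support_radius` Gaussian radii (`support_radius * e^sigma`
#' retinal units).
#'
#' @param n_theta Number of orientation samples in `[0, pi)`.
#' @param sigma_grid Strictly increasing log-scale samples (>= 2 values).
#' @param support_radius Truncation radius in units of `e^sigma`.
#' @param pixel_size Retinal units per pixel of the images to be lifted.
#' @return An object of class `gabor_bank` with the kernel stack and an
#'   initially unset width calibration (see [calibrate_bank()]).
#' @export
gabor_bank <- function(n_theta = 16, sigma_grid = seq(-1, 1.8, length.out = 8),
                       support_radius = 3, pixel_size = 1) {
  stopifnot(n_theta >= 2, length(sigma_grid) >= 2, all(diff(sigma_grid) > 0),
            support_radius > 0, pixel_size > 0)
  theta_grid <- seq(0, pi, length.out = n_theta + 1)[seq_len(n_theta)]
  kernels <- vector("list", n_theta * length(sigma_grid))
  dim(kernels) <- c(n_theta, length(sigma_grid))
  for (is in seq_along(sigma_grid)) {
    s <- sigma_grid[is]
    r <- max(2L, ceiling(support_radius * exp(s) / pixel_size))
    off <- (-r):r
    # integrate the profile over each pixel's area (midpoint rule on an
    # ss x ss subgrid) so sub-pixel scales are not aliased by point sampling
    ss <- min(8L, max(1L, ceiling(3 * pixel_size / exp(s))))
    sub <- (seq_len(ss) - (ss + 1) / 2) / ss
    for (it in seq_len(n_theta)) {
      k <- matrix(0, length(off), length(off))
      for (a in sub) for (b in sub) {
        dx <- outer(rep(1, length(off)), off + b) * pixel_size
        dy <- -outer(off + a, rep(1, length(off))) * pixel_size
        k <- k + gabor_profile(theta_grid[it], s, dx, dy)
      }
      kernels[[it, is]] <- k / ss^2 * pixel_size^2
    }
  }
  structure(list(theta_grid = theta_grid, sigma_grid = sigma_grid,
                 support_radius = support_radius, pixel_size = pixel_size,
                 kernels = kernels, calibration = NA_real_),
            class = "gabor_bank")
}

#' @export
print.gabor_bank <- function(x, ...) {
  cat(sprintf("<gabor_bank> %d orientations on [0, pi), %d log-scales on [%g, %g]\n",
              length(x$theta_grid), length(x$sigma_grid),
              min(x$sigma_grid), max(x$sigma_grid)))
  if (!is.na(x$calibration))
    cat(sprintf("  width calibration: sigma_hat = ln(width) + %.4f\n",
                x$calibration))
  invisible(x)
}

# circular FFT convolution of a reflectively padded image with one kernel
conv_reflect_fft <- function(img, kernel) {
  nr <- nrow(img); nc <- ncol(img)
  r <- (nrow(kernel) - 1) / 2
  pr <- min(r, nr - 1); pc <- min(r, nc - 1)
  # reflective padding (no edge duplication beyond mirror)
  top <- img[rev(seq_len(pr)), , drop = FALSE]
  bot <- img[nr + 1 - seq_len(pr), , drop = FALSE]
  P <- rbind(top, img, bot)
  left <- P[, rev(seq_len(pc)), drop = FALSE]
  right <- P[, nc + 1 - seq_len(pc), drop = FALSE]
  P <- cbind(left, P, right)
  NR <- nrow(P); NC <- ncol(P)
  K <- matrix(0, NR, NC)
  off <- (-r):r
  K[((off %% NR) + 1), ] <- 0  # no-op, keeps shape explicit
  for (i in seq_along(off)) {
    ri <- (off[i] %% NR) + 1
    ci <- (off %% NC) + 1
    K[ri, ci] <- kernel[i, ]
  }
  C <- Re(stats::fft(stats::fft(P) * stats::fft(K), inverse = TRUE)) / (NR * NC)
  C[pr + seq_len(nr), pc + seq_len(nc), drop = FALSE]
}

#' Lift an image to the similarity group
#'
#' Convolves the image with every profile of the bank, producing the 4-D
#' orientation-scale score `O(x, y, theta, sigma)` whose fiberwise maxima
#' select the engrafted orientation and log-thickness of local contours.
#' Linear in the input; computed by FFT convolution with reflective padding.
#'
#' @param img An [image_grid()] (or plain matrix, taken at `pixel_size` 1).
#' @param bank A [gabor_bank()] with matching `pixel_size`.
#' @return An object of class `lifted_image` holding the response array
#'   (dimensions row, column, orientation, scale) and both grids.
#' @export
lift_image <- function(img, bank) {
  if (is.matrix(img)) img <- image_grid(img)
  stopifnot(inherits(img, "image_grid"), inherits(bank, "gabor_bank"))
  if (abs(img$pixel_size - bank$pixel_size) > 1e-12)
    stop("bank was built for pixel_size ", bank$pixel_size,
         " but image has ", img$pixel_size, call. = FALSE)
  nt <- length(bank$theta_grid); ns <- length(bank$sigma_grid)
  I <- img$intensities
  O <- array(0, dim = c(nrow(I), ncol(I), nt, ns))
  for (is in seq_len(ns)) for (it in seq_len(nt))
    O[, , it, is] <- conv_reflect_fft(I, bank$kernels[[it, is]])
  structure(list(responses = O, image = img, bank = bank),
            class = "lifted_image")
}

#' @export
print.lifted_image <- function(x, ...) {
  d <- dim(x$responses)
  cat(sprintf("<lifted_image> %d x %d pixels x %d orientations x %d scales\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}

# one-dimensional 3-point parabolic peak refinement; returns offset in [-1, 1]
parabolic_offset <- function(ym, y0, yp) {
  den <- ym - 2 * y0 + yp
  if (abs(den) < 1e-300) return(0)
  off <- 0.5 * (ym - yp) / den
  max(-1, min(1, off))
}

#' Select orientation and scale by maximum response
#'
#' Fiberwise argmax of the absolute response `|O(x, y, ., .)|` at one pixel
#' (the even filters flip sign with contrast polarity, so magnitude is
#' compared).  Exact ties are broken by the smallest `(theta, sigma)` pair in
#' lexicographic grid order; an all-zero fiber is flagged `"no_response"`.
#' With `refine = TRUE` the grid maximum is sharpened by separable 3-point
#' parabolic interpolation (periodic in `theta`, clamped in `sigma`).
#'
#' @param lifted A [lift_image()] result.
#' @param col,row Pixel indices (column = x direction, row = y direction,
#'   row 1 at the top).
#' @param refine Sub-grid refinement of the maximum.
#' @return A one-row tibble with `theta`, `sigma`, grid indices
#'   `theta_index`, `sigma_index`, the winning `response`, and `flag`
#'   (`"ok"`, `"tie"` or `"no_response"`).
#' @export
select_orientation_scale <- function(lifted, col, row, refine = FALSE) {
  stopifnot(inherits(lifted, "lifted_image"))
  d <- dim(lifted$responses)
  stopifnot(row >= 1, row <= d[1], col >= 1, col <= d[2])
  fib <- lifted$responses[row, col, , ]
  A <- abs(fib)
  bank <- lifted$bank
  if (max(A) == 0)
    return(tibble::tibble(theta = NA_real_, sigma = NA_real_,
                          theta_index = NA_integer_, sigma_index = NA_integer_,
                          response = 0, flag = "no_response"))
  hits <- which(A >= max(A) * (1 - 1e-12), arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  it <- hits[1, 1]; is <- hits[1, 2]
  flag <- if (nrow(hits) > 1) "tie" else "ok"
  theta <- bank$theta_grid[it]; sigma <- bank$sigma_grid[is]
  if (refine && flag == "ok") {
    nt <- d[3]; ns <- d[4]
    # theta is periodic with period pi on the sampled grid
    itm <- if (it == 1) nt else it - 1
    itp <- if (it == nt) 1 else it + 1
    dth <- pi / nt
    theta <- theta + parabolic_offset(A[itm, is], A[it, is], A[itp, is]) * dth
    if (is > 1 && is < ns) {
      ds <- bank$sigma_grid[is + 1] - bank$sigma_grid[is]
      sigma <- sigma +
        parabolic_offset(A[it, is - 1], A[it, is], A[it, is + 1]) * ds
    }
  }
  tibble::tibble(theta = theta, sigma = sigma,
                 theta_index = as.integer(it), sigma_index = as.integer(is),
                 response = fib[it, is], flag = flag)
}

# responses over the whole bank at selected pixels only (direct correlation
# against the padded image; the even kernels make convolution = correlation)
responses_at_pixels <- function(img, bank, rows, cols) {
  I <- img$intensities
  nr <- nrow(I); nc <- ncol(I)
  rmax <- max(vapply(seq_along(bank$sigma_grid), function(is)
    (nrow(bank$kernels[[1, is]]) - 1) / 2, numeric(1)))
  # reflective pad once by the largest radius
  idx <- function(i, n) {
    i <- abs(i - 1) + 1
    i <- ifelse(i > n, 2 * n - i + 1, i)
    pmin(pmax(i, 1), n)
  }
  pr <- idx(seq(1 - rmax, nr + rmax), nr)
  pc <- idx(seq(1 - rmax, nc + rmax), nc)
  P <- I[pr, pc, drop = FALSE]
  nt <- length(bank$theta_grid); ns <- length(bank$sigma_grid)
  out <- array(0, dim = c(length(rows), nt, ns))
  for (is in seq_len(ns)) {
    r <- (nrow(bank$kernels[[1, is]]) - 1) / 2
    for (k in seq_along(rows)) {
      patch <- P[rmax + rows[k] + (-r):r, rmax + cols[k] + (-r):r]
      for (it in seq_len(nt))
        out[k, it, is] <- sum(patch * bank$kernels[[it, is]])
    }
  }
  out
}

#' Boundary configurations of contours entering a damaged region
#'
#' Finds, on the ring of intact pixels bordering a damage mask, the places
#' where image contours touch the damage, and lifts each to a SIM(2)
#' configuration `(x, y, theta, sigma)` via the maximum-response selection.
#' Ring pixels whose peak response falls below `response_frac` of the
#' strongest ring response are dropped; the survivors are clustered into
#' 8-connected components (one per contour crossing) and each component
#' contributes its strongest pixel.
#'
#' Filters centered right at the cut face see the contour termination rather
#' than the contour, so probing happens on a ring `probe_offset` pixels away
#' from the mask (Chebyshev distance), where the selected orientation and
#' scale have stabilized.
#'
#' @param img An [image_grid()].
#' @param mask Logical matrix of the same shape, `TRUE` inside the damage.
#' @param bank A [gabor_bank()].
#' @param response_frac Relative response threshold in `(0, 1)`.
#' @param probe_offset Ring distance from the mask, in pixels (0 = adjacent).
#' @param refine Passed to the orientation/scale selection.
#' @return A tibble with retinal `x`, `y`, `theta` (in `[0, pi)`, direction
#'   unresolved), `sigma`, pixel `row`/`col` and `response`; zero rows when
#'   no contour touches the mask.
#' @export
extract_boundary_configurations <- function(img, mask, bank,
                                            response_frac = 0.25,
                                            probe_offset = 3,
                                            refine = TRUE) {
  if (is.matrix(img)) img <- image_grid(img)
  stopifnot(inherits(img, "image_grid"), is.matrix(mask),
            all(dim(mask) == dim(img$intensities)))
  mask <- mask > 0
  if (all(mask)) stop("mask covers the whole image", call. = FALSE)
  if (!any(mask)) return(boundary_config_empty())
  nr <- nrow(mask); nc <- ncol(mask)
  shift <- function(m, dr, dc) {
    out <- matrix(FALSE, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
    out[which(ok_r), which(ok_c)] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  dilate8 <- function(m) {
    out <- m
    for (dr in -1:1) for (dc in -1:1)
      if (dr != 0 || dc != 0) out <- out | shift(m, dr, dc)
    out
  }
  grown <- mask
  for (k in seq_len(probe_offset)) grown <- dilate8(grown)
  ring <- dilate8(grown) & !grown
  ridx <- which(ring, arr.ind = TRUE)
  if (nrow(ridx) == 0) return(boundary_config_empty())
  resp <- responses_at_pixels(img, bank, ridx[, 1], ridx[, 2])
  strength <- apply(abs(resp), 1, max)
  if (max(strength) == 0) return(boundary_config_empty())
  keep <- strength >= response_frac * max(strength) & strength > 1e-12
  if (!any(keep)) return(boundary_config_empty())
  kidx <- ridx[keep, , drop = FALSE]
  kstr <- strength[keep]
  # 8-connected components among kept ring pixels
  comp <- integer(nrow(kidx)); cur <- 0
  for (i in seq_len(nrow(kidx))) {
    if (comp[i] > 0) next
    cur <- cur + 1
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      j <- queue[[1]]; queue <- queue[-1]
      nb <- which(comp == 0 &
                  abs(kidx[, 1] - kidx[j, 1]) <= 1 &
                  abs(kidx[, 2] - kidx[j, 2]) <= 1)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  picks <- vapply(seq_len(cur), function(cc) {
    members <- which(comp == cc)
    members[which.max(kstr[members])]
  }, integer(1))
  # full bank selection at the picked pixels via the standard lift machinery
  kresp <- resp[keep, , , drop = FALSE]
  out <- purrr::map_dfr(picks, function(i) {
    row <- kidx[i, 1]; col <- kidx[i, 2]
    fib <- kresp[i, , ]
    sel <- select_from_fiber(fib, bank, refine)
    xy <- pixel_xy(img, row, col)
    tibble::tibble(x = unname(xy$x), y = unname(xy$y),
                   theta = unname(sel$theta), sigma = unname(sel$sigma),
                   row = as.integer(row), col = as.integer(col),
                   response = unname(sel$response))
  })
  out
}

boundary_config_empty <- function() {
  tibble::tibble(x = numeric(), y = numeric(), theta = numeric(),
                 sigma = numeric(), row = integer(), col = integer(),
                 response = numeric())
}

# shared fiber argmax used by select_orientation_scale and the boundary
# extractor (which computes responses only at ring pixels)
select_from_fiber <- function(fib, bank, refine = FALSE) {
  A <- abs(fib)
  hits <- which(A >= max(A) * (1 - 1e-12), arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  it <- hits[1, 1]; is <- hits[1, 2]
  theta <- bank$theta_grid[it]; sigma <- bank$sigma_grid[is]
  if (refine && nrow(hits) == 1) {
    nt <- length(bank$theta_grid); ns <- length(bank$sigma_grid)
    itm <- if (it == 1) nt else it - 1
    itp <- if (it == nt) 1 else it + 1
    theta <- theta + parabolic_offset(A[itm, is], A[it, is], A[itp, is]) *
      (pi / nt)
    if (is > 1 && is < ns) {
      ds <- bank$sigma_grid[is + 1] - bank$sigma_grid[is]
      sigma <- sigma +
        parabolic_offset(A[it, is - 1], A[it, is], A[it, is + 1]) * ds
    }
  }
  list(theta = theta, sigma = sigma, response = A[it, is])
}

#' Calibrate bank log-scales against stroke widths
#'
#' The fiber argmax fixes `sigma` only up to the bank's internal scale
#' normalization; this measures the offset once on a reference horizontal bar
#' of known width and stores `calibration = sigma_hat - ln(width)`, so that a
#' measured `sigma_hat` converts to a physical stroke width
#' `exp(sigma_hat - calibration)` (retinal units).
#'
#' @param bank A [gabor_bank()].
#' @param ref_width Reference bar width in retinal units.
#' @return The bank with `calibration` filled in.
#' @export
calibrate_bank <- function(bank, ref_width = 3) {
  stopifnot(inherits(bank, "gabor_bank"))
  n <- max(49, ceiling(12 * ref_width / bank$pixel_size))
  if (n %% 2 == 0) n <- n + 1  # odd canvas: a pixel row sits on the centerline
  half <- (n - 1) / 2 * bank$pixel_size
  fx <- make_curve_image(waypoints = cbind(c(-half, half), c(0, 0)),
                         widths = c(ref_width, ref_width),
                         nx = n, ny = n, pixel_size = bank$pixel_size)
  L <- lift_image(fx$image, bank)
  ctr <- xy_pixel(fx$image, 0, 0)
  sel <- select_orientation_scale(L, ctr$col, ctr$row, refine = TRUE)
  bank$calibration <- sel$sigma - log(ref_width)
  bank
}
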