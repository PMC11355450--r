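#' Rasterize a synthetic curve image with ground truth
#'
#' Draws a polyline stroke with linearly interpolated width onto a fresh
#' canvas and returns, alongside the image, the per-arc ground truth
#' `(x, y, theta, sigma = ln width)` that lifting tests compare against.
#' A pixel is inside the stroke when its distance to the polyline is at most
#' half the local width.  Optional Gaussian pixel noise is seeded and
#' clipped at zero so intensities stay nonnegative.
#'
#' @param waypoints Two-column matrix (or data frame with `x`, `y`) of
#'   retinal-plane waypoints, at least 2 rows.
#' @param widths Stroke width (retinal units) at each waypoint, `> 0`;
#'   recycled if scalar.
#' @param nx,ny Canvas size in pixels (columns, rows).
#' @param pixel_size Retinal units per pixel.
#' @param origin Retinal coordinates of the canvas center.
#' @param intensity Stroke gray level in `(0, 1]`.
#' @param noise_sd Standard deviation of additive pixel noise (0 = none).
#' @param seed Integer seed used when `noise_sd > 0`.
#' @param truth_step Arc-length step of the ground-truth samples.
#' @return A list with `image` (an [image_grid()]) and `truth` (a tibble
#'   `x`, `y`, `theta` in `[0, pi)`, `sigma`).
#' @export
make_curve_image <- function(waypoints, widths, nx = 64, ny = 64,
                             pixel_size = 1, origin = c(0, 0),
                             intensity = 1, noise_sd = 0, seed = 1,
                             truth_step = 0.5) {
  if (is.data.frame(waypoints)) waypoints <- cbind(waypoints$x, waypoints$y)
  stopifnot(is.matrix(waypoints), ncol(waypoints) == 2, nrow(waypoints) >= 2,
            intensity > 0, intensity <= 1)
  widths <- rep_len(as.numeric(widths), nrow(waypoints))
  stopifnot(all(widths > 0))
  seg_len <- sqrt(rowSums((waypoints[-1, , drop = FALSE] -
                           waypoints[-nrow(waypoints), , drop = FALSE])^2))
  if (all(seg_len < 1e-12)) stop("degenerate curve: zero total length",
                                 call. = FALSE)

  grid <- image_grid(matrix(0, ny, nx), pixel_size, origin)
  cc <- pixel_xy(grid, outer(seq_len(ny), rep(1, nx)),
                 outer(rep(1, ny), seq_len(nx)))
  px <- cc$x; py <- cc$y

  cover <- matrix(0, ny, nx)
  truth <- list()
  for (s in seq_len(nrow(waypoints) - 1)) {
    if (seg_len[s] < 1e-12) next
    a <- waypoints[s, ]; b <- waypoints[s + 1, ]
    wa <- widths[s]; wb <- widths[s + 1]
    d <- b - a
    # projection parameter of each pixel onto the segment, clamped to [0, 1]
    tt <- ((px - a[1]) * d[1] + (py - a[2]) * d[2]) / sum(d^2)
    tt <- pmin(pmax(tt, 0), 1)
    dist <- sqrt((px - (a[1] + tt * d[1]))^2 + (py - (a[2] + tt * d[2]))^2)
    wloc <- wa + tt * (wb - wa)
    # pixel coverage by the stroke (linear edge ramp one pixel wide), so the
    # rasterized mass matches the nominal width instead of inflating by ~1 px
    cover <- pmax(cover,
                  pmin(1, pmax(0, (wloc / 2 - dist) / pixel_size + 0.5)))
    ts <- seq(0, 1, by = min(1, truth_step / seg_len[s]))
    truth[[s]] <- tibble::tibble(
      x = a[1] + ts * d[1], y = a[2] + ts * d[2],
      theta = atan2(d[2], d[1]) %% pi,
      sigma = log(wa + ts * (wb - wa)))
  }
  img <- intensity * cover
  if (noise_sd > 0) {
    old <- .Random.seed2_save()
    on.exit(.Random.seed2_restore(old), add = TRUE)
    set.seed(seed)
    img <- pmax(img + matrix(stats::rnorm(nx * ny, sd = noise_sd), ny, nx), 0)
  }
  list(image = image_grid(img, pixel_size, origin),
       truth = dplyr::bind_rows(truth))
}

# save/restore the global RNG state so seeded fixtures do not disturb callers
.Random.seed2_save <- function() {
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
}
.Random.seed2_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
}

#' Corrupt an image with a disc-shaped damage region
#'
#' Sets every pixel inside a disc to the background level and returns the
#' binary damage mask alongside; pixels outside the disc are untouched, so
#' the corrupted image plus the mask reconstruct the original exactly off
#' the disc.  Applying the same disc twice is idempotent.
#'
#' @param img An [image_grid()] (or plain matrix).
#' @param center Length-2 retinal coordinates of the disc center.
#' @param radius Disc radius in retinal units, `> 0`.
#' @param background Intensity written inside the disc.
#' @return A list with `image` (corrupted [image_grid()]) and `mask`
#'   (logical matrix, `TRUE` inside the disc).
#' @export
corrupt_with_disc <- function(img, center, radius, background = 0) {
  if (is.matrix(img)) img <- image_grid(img)
  stopifnot(inherits(img, "image_grid"), length(center) == 2)
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  nr <- nrow(img$intensities); nc <- ncol(img$intensities)
  cc <- pixel_xy(img, outer(seq_len(nr), rep(1, nc)),
                 outer(rep(1, nr), seq_len(nc)))
  mask <- (cc$x - center[1])^2 + (cc$y - center[2])^2 <= radius^2
  if (!any(mask)) stop("disc does not intersect the canvas", call. = FALSE)
  out <- img$intensities
  out[mask] <- background
  list(image = image_grid(out, img$pixel_size, img$origin), mask = mask)
}
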