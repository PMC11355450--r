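#' Read and write grayscale images
#'
#' PNG (8/16-bit) and TIFF files are read into an [image_grid()] with
#' intensities normalized to `[0, 1]`; color images are averaged to
#' grayscale.  Writing clips to `[0, 1]`.
#'
#' @param path File path; format chosen by extension (`.png`, `.tif(f)`).
#' @param pixel_size,origin Grid geometry to attach on read.
#' @return `read_image()`: an [image_grid()]; `write_image()`: `path`,
#'   invisibly.
#' @export
read_image <- function(path, pixel_size = 1, origin = c(0, 0)) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(arr)) == 3) arr <- apply(arr[, , seq_len(min(3, dim(arr)[3])),
                                              drop = FALSE], c(1, 2), mean)
  image_grid(arr, pixel_size = pixel_size, origin = origin)
}

#' @rdname read_image
#' @param img An [image_grid()] or matrix.
#' @export
write_image <- function(img, path) {
  m <- if (inherits(img, "image_grid")) img$intensities else img
  m <- pmin(pmax(m, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(m, path),
         tif = ,
         tiff = tiff::writeTIFF(m, path),
         stop("unsupported image format: .", ext, call. = FALSE))
  invisible(path)
}

#' Serialize configurations and covectors
#'
#' Configurations travel as JSON objects with fields `x`, `y`, `theta`
#' (radians), `sigma`, and as CSV rows with the same columns; covectors as
#' JSON objects `h1`..`h4`.  Trajectories round-trip through CSV with
#' columns `t`, `x`, `y`, `theta`, `sigma`, `h1`..`h4`, `H`, `g1`, `g2`.
#'
#' @param q A configuration tibble; @param h a covector tibble;
#'   @param traj an `sr_trajectory`; @param path a file path.
#' @return Writers return `path` invisibly; readers return tibbles.
#' @export
write_configurations_json <- function(q, path) {
  jsonlite::write_json(as_sim2(q), path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_configurations_json
#' @export
read_configurations_json <- function(path) {
  as_sim2(tibble::as_tibble(jsonlite::fromJSON(path)))
}

#' @rdname write_configurations_json
#' @export
write_configurations_csv <- function(q, path) {
  utils::write.csv(as_sim2(q), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_configurations_json
#' @export
read_configurations_csv <- function(path) {
  as_sim2(tibble::as_tibble(utils::read.csv(path)))
}

#' @rdname write_configurations_json
#' @export
write_covector_json <- function(h, path) {
  jsonlite::write_json(as_covector(h), path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_configurations_json
#' @export
read_covector_json <- function(path) {
  as_covector(tibble::as_tibble(jsonlite::fromJSON(path)))
}

#' @rdname write_configurations_json
#' @export
write_trajectory_csv <- function(traj, path) {
  cols <- c("t", "x", "y", "theta", "sigma", "h1", "h2", "h3", "h4",
            "H", "g1", "g2")
  utils::write.csv(as.data.frame(traj)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_configurations_json
#' @export
read_trajectory_csv <- function(path) {
  d <- tibble::as_tibble(utils::read.csv(path))
  new_trajectory(d$t, d$x, d$y, d$theta, d$sigma, d$h1, d$h2, d$h3, d$h4,
                 h0 = covector(d$h1[1], d$h2[1], d$h3[1], d$h4[1]))
}

#' Serialize a grouping scene to JSON
#'
#' The scene (foreground, background, parameters including the seed) is
#' written as deterministic JSON: the same seed yields byte-identical files.
#'
#' @param scene A [build_grouping_scene()] result; @param path file path.
#' @return `path` (writer) or a `grouping_scene` (reader).
#' @export
write_scene_json <- function(scene, path) {
  stopifnot(inherits(scene, "grouping_scene"))
  jsonlite::write_json(list(foreground = scene$foreground,
                            background = scene$background,
                            params = scene$params),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_scene_json
#' @export
read_scene_json <- function(path) {
  d <- jsonlite::fromJSON(path)
  structure(list(foreground = tibble::as_tibble(d$foreground),
                 background = tibble::as_tibble(d$background),
                 params = d$params),
            class = "grouping_scene")
}
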