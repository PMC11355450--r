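#' Plot a geodesic trajectory
#'
#' Planar projection of the trajectory, colored by log-thickness; the
#' stroke's physical width grows with `exp(sigma)`.
#'
#' @param object An `sr_trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sr_trajectory
#' @export
autoplot.sr_trajectory <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y,
                                       color = .data$sigma)) +
    ggplot2::geom_path(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x", y = "y", color = expression(sigma),
                  title = "Sub-Riemannian geodesic (planar projection)") +
    ggplot2::theme_minimal()
}

#' Plot an association-field fan
#'
#' @param af The tibble returned by [association_field()].
#' @param t_show Clip curves at this arc length for display.
#' @return A ggplot.
#' @export
plot_association_field <- function(af, t_show = Inf) {
  d <- dplyr::filter(af, .data$t <= t_show)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  group = .data$curve_id)) +
    ggplot2::geom_path(alpha = 0.85) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x", y = "y", title = "Association field") +
    ggplot2::theme_minimal()
}

#' Plot a grouping scene
#'
#' Foreground and background elements drawn as oriented bars of length
#' proportional to their thickness `exp(sigma)`.
#'
#' @param object A `grouping_scene`.
#' @param bar_scale Bar length per unit thickness.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot grouping_scene
#' @export
autoplot.grouping_scene <- function(object, bar_scale = 0.08, ...) {
  seg <- function(d, role) {
    L <- bar_scale * exp(d$sigma)
    tibble::tibble(x = d$x - L * cos(d$theta), xend = d$x + L * cos(d$theta),
                   y = d$y - L * sin(d$theta), yend = d$y + L * sin(d$theta),
                   role = role)
  }
  d <- dplyr::bind_rows(seg(object$foreground, "foreground"),
                        seg(object$background, "background"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  xend = .data$xend, yend = .data$yend,
                                  color = .data$role)) +
    ggplot2::geom_segment(linewidth = 0.9) +
    ggplot2::scale_color_manual(values = c(foreground = "#d1495b",
                                           background = "grey40")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x", y = "y", color = NULL,
                  title = "Perceptual grouping by sub-Riemannian proximity") +
    ggplot2::theme_minimal()
}

#' Plot an image grid
#'
#' @param object An [image_grid()].
#' @param ... Unused.
#' @return A ggplot raster of the intensities in retinal coordinates.
#' @method autoplot image_grid
#' @export
autoplot.image_grid <- function(object, ...) {
  nr <- nrow(object$intensities); nc <- ncol(object$intensities)
  cc <- pixel_xy(object, outer(seq_len(nr), rep(1, nc)),
                 outer(rep(1, nr), seq_len(nc)))
  d <- tibble::tibble(x = as.vector(cc$x), y = as.vector(cc$y),
                      intensity = as.vector(object$intensities))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}
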