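#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a shooting result
#'
#' One row per multi-start candidate: initial covector components, arc
#' length, residual, convergence flag, total orientation rotation and
#' whether the candidate survived the winding filter.
#'
#' @param x An `sr_shoot` object.
#' @param ... Unused.
#' @return A tibble of candidates.
#' @method tidy sr_shoot
#' @export
tidy.sr_shoot <- function(x, ...) {
  x$candidates
}

#' Summarize a shooting result
#'
#' One row: the selected candidate's arc length (the sub-Riemannian distance
#' estimate), residual, convergence flag and the number of starts consumed.
#'
#' @param x An `sr_shoot` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance sr_shoot
#' @export
glance.sr_shoot <- function(x, ...) {
  tibble::tibble(T = x$T, residual = x$residual, converged = x$converged,
                 n_starts_used = x$n_starts_used,
                 h1 = x$h0$h1, h2 = x$h0$h2, h3 = x$h0$h3, h4 = x$h0$h4)
}

#' Summarize a trajectory's conservation quality
#'
#' Reports the relative drift of the conserved quantities `H`, `g1`, `g2`
#' over the trajectory, its final configuration and its arc length.
#'
#' @param x An `sr_trajectory`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance sr_trajectory
#' @export
glance.sr_trajectory <- function(x, ...) {
  drift <- function(v) {
    scale <- max(abs(v[1]), 1e-12)
    max(abs(v - v[1])) / scale
  }
  n <- nrow(x)
  tibble::tibble(T = x$t[n], x_end = x$x[n], y_end = x$y[n],
                 theta_end = x$theta[n], sigma_end = x$sigma[n],
                 H_drift = drift(x$H), g1_drift = drift(x$g1),
                 g2_drift = drift(x$g2))
}
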