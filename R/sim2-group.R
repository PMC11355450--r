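#' Wrap angles to the half-open interval (-pi, pi]
#'
#' Orientations on SIM(2) live on the circle; all angle arithmetic in the
#' package goes through this wrap so that antipodal and full-turn
#' configurations compare equal.  Wrapping is idempotent.
#'
#' @param theta Numeric vector of angles in radians.
#' @return Numeric vector of the same length with values in `(-pi, pi]`.
#' @export
#' @examples
#' wrap_angle(c(0, pi, -pi, 2 * pi, 3 * pi / 2))
wrap_angle <- function(theta) {
  theta - 2 * pi * ceiling((theta - pi) / (2 * pi))
}

#' Construct SIM(2) configurations
#'
#' A configuration `q = (x, y, theta, sigma)` collects a retinal position, a
#' contour orientation and a log-thickness (the physical thickness is
#' `kappa = exp(sigma)`).  All arguments recycle, so `sim2(0, 0)` is the
#' identity and vectors build a table of configurations.
#'
#' @param x,y Retinal-plane coordinates (dimensionless).
#' @param theta Orientation in radians; stored wrapped to `(-pi, pi]`.
#' @param sigma Log-scale (log contour thickness).
#' @return A tibble with columns `x`, `y`, `theta`, `sigma`, one row per
#'   configuration.
#' @export
#' @examples
#' sim2(1, 2, pi / 2, log(2))
sim2 <- function(x = 0, y = 0, theta = 0, sigma = 0) {
  tibble::tibble(x = unname(as.numeric(x)), y = unname(as.numeric(y)),
                 theta = unname(wrap_angle(as.numeric(theta))),
                 sigma = unname(as.numeric(sigma)))
}

#' @rdname sim2
#' @export
sim2_identity <- function() sim2(0, 0, 0, 0)

as_sim2 <- function(q) {
  stopifnot(is.data.frame(q), all(c("x", "y", "theta", "sigma") %in% names(q)))
  sim2(q$x, q$y, q$theta, q$sigma)
}

#' Matrix representation of SIM(2)
#'
#' Each configuration maps to the 3x3 matrix
#' \deqn{\begin{pmatrix} e^\sigma\cos\theta & -e^\sigma\sin\theta & x \\
#'                       e^\sigma\sin\theta &  e^\sigma\cos\theta & y \\
#'                       0 & 0 & 1 \end{pmatrix}}
#' and back; the group product and inverse are computed through this
#' representation so there is a single source of truth for the group law.
#'
#' @param q A single-row configuration tibble (see [sim2()]).
#' @return `sim2_matrix()`: a 3x3 numeric matrix. `sim2_from_matrix()`: a
#'   one-row configuration tibble.
#' @export
sim2_matrix <- function(q) {
  q <- as_sim2(q)
  stopifnot(nrow(q) == 1)
  es <- exp(q$sigma)
  matrix(c(es * cos(q$theta), es * sin(q$theta), 0,
           -es * sin(q$theta), es * cos(q$theta), 0,
           q$x, q$y, 1), nrow = 3)
}

#' @rdname sim2_matrix
#' @param m A 3x3 matrix of the representation above.
#' @export
sim2_from_matrix <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == c(3, 3)))
  sigma <- 0.5 * log(m[1, 1]^2 + m[2, 1]^2)
  theta <- atan2(m[2, 1], m[1, 1])
  sim2(m[1, 3], m[2, 3], theta, sigma)
}

#' Group product and inverse on SIM(2)
#'
#' `sim2_multiply(a, b)` composes similarity transformations (apply `b`, then
#' `a`); `sim2_inverse(a)` inverts them.  Both are computed via the 3x3 matrix
#' representation and vectorize over rows (recycling single rows).
#'
#' @param a,b Configuration tibbles (see [sim2()]).
#' @return A configuration tibble.
#' @export
#' @examples
#' sim2_multiply(sim2(0, 0, pi / 2), sim2(1, 0))  # rotate then read off (0, 1)
sim2_multiply <- function(a, b) {
  a <- as_sim2(a); b <- as_sim2(b)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1 && n > 1) a <- a[rep(1, n), ]
  if (nrow(b) == 1 && n > 1) b <- b[rep(1, n), ]
  stopifnot(nrow(a) == nrow(b))
  ea <- exp(a$sigma)
  sim2(a$x + ea * (cos(a$theta) * b$x - sin(a$theta) * b$y),
       a$y + ea * (sin(a$theta) * b$x + cos(a$theta) * b$y),
       a$theta + b$theta,
       a$sigma + b$sigma)
}

#' @rdname sim2_multiply
#' @export
sim2_inverse <- function(a) {
  a <- as_sim2(a)
  ei <- exp(-a$sigma)
  sim2(-ei * (cos(a$theta) * a$x + sin(a$theta) * a$y),
       -ei * (-sin(a$theta) * a$x + cos(a$theta) * a$y),
       -a$theta, -a$sigma)
}

#' Left-invariant frame on SIM(2)
#'
#' Components of the left-invariant fields X1..X4 at a configuration, in the
#' `(x, y, theta, sigma)` chart:
#' `X1 = e^sigma (cos theta, sin theta, 0, 0)`,
#' `X2 = e^sigma (-sin theta, cos theta, 0, 0)`, `X3 = d/dtheta`,
#' `X4 = d/dsigma`.  The horizontal distribution is spanned by X1, X3, X4.
#'
#' @param q A single-row configuration tibble.
#' @return A tibble with columns `field` (`"X1"`..`"X4"`) and the chart
#'   components `dx`, `dy`, `dtheta`, `dsigma`.
#' @export
frame_components <- function(q) {
  q <- as_sim2(q)
  stopifnot(nrow(q) == 1)
  es <- exp(q$sigma)
  tibble::tibble(
    field  = c("X1", "X2", "X3", "X4"),
    dx     = c(es * cos(q$theta), -es * sin(q$theta), 0, 0),
    dy     = c(es * sin(q$theta),  es * cos(q$theta), 0, 0),
    dtheta = c(0, 0, 1, 0),
    dsigma = c(0, 0, 0, 1))
}

#' Contact one-form on SIM(2)
#'
#' Evaluates `omega = e^{-sigma} (-sin theta dx + cos theta dy)` at `q` on a
#' chart velocity `v`.  A velocity is horizontal (admissible for a neural
#' connection) exactly when the pairing vanishes; `omega(X2) = 1` normalizes
#' the form.
#'
#' @param q A single-row configuration tibble.
#' @param v Numeric length-4 chart velocity `(dx, dy, dtheta, dsigma)`.
#' @return Scalar value of the pairing.
#' @export
contact_pairing <- function(q, v) {
  q <- as_sim2(q)
  stopifnot(nrow(q) == 1, length(v) == 4)
  exp(-q$sigma) * (-sin(q$theta) * v[1] + cos(q$theta) * v[2])
}

#' Sub-Riemannian speed of a control vector
#'
#' The metric makes X1, X3, X4 orthogonal with weights 1, alpha, beta, so a
#' horizontal velocity `u1 X1 + u3 X3 + u4 X4` has length
#' `sqrt(u1^2 + alpha^2 u3^2 + beta^2 u4^2)`; integrating it along a curve
#' gives the curve's sub-Riemannian length.  Vectorized over controls.
#'
#' @param u1,u3,u4 In-plane tangential speed, orientation rate, scale rate.
#' @param alpha,beta Positive metric weights (defaults 1, the model case).
#' @return Numeric vector of speeds.
#' @export
horizontal_speed <- function(u1, u3, u4, alpha = 1, beta = 1) {
  stopifnot(alpha > 0, beta > 0)
  sqrt(u1^2 + alpha^2 * u3^2 + beta^2 * u4^2)
}

#' Structure constants of the left-invariant frame
#'
#' The nonzero Lie brackets of the frame are `[X1,X3] = -X2`,
#' `[X1,X4] = -X1`, `[X2,X3] = X1`, `[X2,X4] = -X2`; every other pair
#' commutes.  Returned as a table of bracket coefficients
#' `[Xi, Xj] = sum_k c_k X_k`.
#'
#' @return A tibble with columns `i`, `j` (field indices, `i < j`) and the
#'   coefficients `c1`..`c4`.
#' @export
structure_constants <- function() {
  out <- tidyr::expand_grid(i = 1:4, j = 1:4) |> dplyr::filter(.data$i < .data$j)
  cs <- matrix(0, nrow(out), 4)
  set <- function(i, j, k, v) cs[out$i == i & out$j == j, k] <<- v
  set(1, 3, 2, -1)  # [X1,X3] = -X2
  set(1, 4, 1, -1)  # [X1,X4] = -X1
  set(2, 3, 1,  1)  # [X2,X3] =  X1
  set(2, 4, 2, -1)  # [X2,X4] = -X2
  colnames(cs) <- paste0("c", 1:4)
  dplyr::bind_cols(out, tibble::as_tibble(cs))
}

# Numeric Lie bracket [Xi, Xj] at q by central finite differences of the
# coordinate frame fields: (DXj) Xi - (DXi) Xj with the Jacobians of the
# component maps q -> Xi(q).
lie_bracket_numeric <- function(i, j, q, step = 1e-5) {
  q <- as_sim2(q)
  fld <- function(k, qq) as.numeric(frame_components(qq)[k, c("dx", "dy", "dtheta", "dsigma")])
  jac <- function(k) {
    J <- matrix(0, 4, 4)
    q0 <- as.numeric(q[1, c("x", "y", "theta", "sigma")])
    for (c in 1:4) {
      qp <- q0; qp[c] <- qp[c] + step
      qm <- q0; qm[c] <- qm[c] - step
      J[, c] <- (fld(k, sim2(qp[1], qp[2], qp[3], qp[4])) -
                 fld(k, sim2(qm[1], qm[2], qm[3], qm[4]))) / (2 * step)
    }
    J
  }
  as.numeric(jac(j) %*% fld(i, q) - jac(i) %*% fld(j, q))
}

# Express a chart velocity in the left-invariant frame at q (coefficients on
# X1..X4); used to verify Hormander spans and bracket identities.
frame_coefficients <- function(q, v) {
  fr <- frame_components(q)
  B <- t(as.matrix(fr[, c("dx", "dy", "dtheta", "dsigma")]))
  as.numeric(solve(B, v))
}
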