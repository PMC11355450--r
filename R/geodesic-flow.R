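#' Construct covectors in the left-invariant frame
#'
#' Momenta `h = (h1, h2, h3, h4)` are the pairings of the chart momentum with
#' the left-invariant frame fields X1..X4.  Arc-length normal extremals start
#' on the level set `C = {h : h1^2 + h3^2 + h4^2 = 1}`.
#'
#' @param h1,h2,h3,h4 Numeric momentum components (recycled).
#' @return A tibble with columns `h1`..`h4`.
#' @export
covector <- function(h1 = 0, h2 = 0, h3 = 0, h4 = 0) {
  tibble::tibble(h1 = unname(as.numeric(h1)), h2 = unname(as.numeric(h2)),
                 h3 = unname(as.numeric(h3)), h4 = unname(as.numeric(h4)))
}

as_covector <- function(h) {
  if (is.numeric(h) && length(h) == 4 && is.null(dim(h)))
    return(covector(h[1], h[2], h[3], h[4]))
  stopifnot(is.data.frame(h), all(c("h1", "h2", "h3", "h4") %in% names(h)))
  covector(h$h1, h$h2, h$h3, h$h4)
}

# h1^2 + h3^2 + h4^2, the conserved quadratic Hamiltonian (model case).
hamiltonian_level <- function(h) {
  h <- as_covector(h)
  h$h1^2 + h$h3^2 + h$h4^2
}

#' Pontryagin function of a control
#'
#' The pairing `H_u = u1 h1 + u3 h3 + u4 h4` between a horizontal control and
#' a covector.  Over the arc-length control set `u1^2 + u3^2 + u4^2 = 1` it is
#' maximized by `u` proportional to `(h1, h3, h4)`, which yields the extremal
#' controls `u1 = h1, u3 = h3, u4 = h4` on the level set `C = 1`.
#'
#' @param h A covector (tibble or numeric length 4).
#' @param u1,u3,u4 Control components (recycled).
#' @return Numeric vector of pairings.
#' @export
pontryagin_value <- function(h, u1, u3, u4) {
  h <- as_covector(h)
  u1 * h$h1 + u3 * h$h3 + u4 * h$h4
}

#' Right-hand side of the normal extremal flow
#'
#' The coupled horizontal/vertical system for normal Pontryagin extremals in
#' the model case (unit metric weights):
#' `xdot = h1 e^sigma cos theta`, `ydot = h1 e^sigma sin theta`,
#' `thetadot = h3`, `sigmadot = h4`, `h1dot = h3 h2 + h4 h1`,
#' `h2dot = -h3 h1 + h4 h2`, `h3dot = -h1 h2`, `h4dot = -h1^2`.
#' This pure-R evaluation mirrors the compiled right-hand side used by the
#' integrator and is exposed for inspection and testing.
#'
#' @param q A single-row configuration tibble.
#' @param h A covector.
#' @return Named numeric length-8 derivative
#'   `(dx, dy, dtheta, dsigma, dh1, dh2, dh3, dh4)`.
#' @export
normal_rhs <- function(q, h) {
  q <- as_sim2(q); h <- as_covector(h)
  stopifnot(nrow(q) == 1, nrow(h) == 1)
  es <- exp(q$sigma)
  c(dx = h$h1 * es * cos(q$theta),
    dy = h$h1 * es * sin(q$theta),
    dtheta = h$h3,
    dsigma = h$h4,
    dh1 = h$h3 * h$h2 + h$h4 * h$h1,
    dh2 = -h$h3 * h$h1 + h$h4 * h$h2,
    dh3 = -h$h1 * h$h2,
    dh4 = -h$h1^2)
}

#' First integrals of the normal flow
#'
#' Along every normal extremal the Hamiltonian `H = h1^2 + h3^2 + h4^2` and
#' the two momenta induced by right-invariant fields,
#' `g1 = e^{-sigma}(h1 cos theta - h2 sin theta)` and
#' `g2 = e^{-sigma}(h2 cos theta + h1 sin theta)`, are conserved.  `g1`, `g2`
#' equal the constant chart momenta `p1`, `p2`.  Vectorized over rows.
#'
#' @param q Configuration tibble.
#' @param h Covector tibble (same number of rows, or length-4 numeric).
#' @return A tibble with columns `H`, `g1`, `g2`.
#' @export
first_integrals <- function(q, h) {
  q <- as_sim2(q); h <- as_covector(h)
  es <- exp(-q$sigma)
  tibble::tibble(
    H  = h$h1^2 + h$h3^2 + h$h4^2,
    g1 = es * (h$h1 * cos(q$theta) - h$h2 * sin(q$theta)),
    g2 = es * (h$h2 * cos(q$theta) + h$h1 * sin(q$theta)))
}

#' Convert between frame momenta h and chart momenta p
#'
#' At a configuration `q` the left-invariant momenta are
#' `h1 = e^sigma (p1 cos theta + p2 sin theta)`,
#' `h2 = e^sigma (-p1 sin theta + p2 cos theta)`, `h3 = p3`, `h4 = p4`
#' (pairings with the frame fields), with inverse
#' `p1 = e^{-sigma} (h1 cos theta - h2 sin theta)`,
#' `p2 = e^{-sigma} (h1 sin theta + h2 cos theta)`.  The two maps are mutually
#' inverse linear maps at each `q`; `p3 = h3` and `p4 = h4` always.
#'
#' @param h Covector tibble; @param p tibble with columns `p1`..`p4`.
#' @param q Configuration tibble (rows recycled against `h`/`p`).
#' @return `chart_momentum()`: tibble `p1`..`p4`; `frame_momentum()`: tibble
#'   `h1`..`h4`.
#' @export
chart_momentum <- function(h, q) {
  h <- as_covector(h); q <- as_sim2(q)
  es <- exp(-q$sigma)
  tibble::tibble(
    p1 = es * (h$h1 * cos(q$theta) - h$h2 * sin(q$theta)),
    p2 = es * (h$h1 * sin(q$theta) + h$h2 * cos(q$theta)),
    p3 = h$h3, p4 = h$h4)
}

#' @rdname chart_momentum
#' @export
frame_momentum <- function(p, q) {
  stopifnot(is.data.frame(p), all(c("p1", "p2", "p3", "p4") %in% names(p)))
  q <- as_sim2(q)
  es <- exp(q$sigma)
  covector(es * (p$p1 * cos(q$theta) + p$p2 * sin(q$theta)),
           es * (-p$p1 * sin(q$theta) + p$p2 * cos(q$theta)),
           p$p3, p$p4)
}

# Assemble a trajectory tibble from an integration/closed-form sample matrix.
new_trajectory <- function(t, x, y, theta, sigma, h1, h2, h3, h4, h0,
                           cut_time = NA_real_) {
  q <- tibble::tibble(x = x, y = y, theta = theta, sigma = sigma)
  h <- covector(h1, h2, h3, h4)
  fi <- first_integrals(q, h)
  out <- tibble::tibble(t = t, x = x, y = y, theta = theta, sigma = sigma,
                        h1 = h1, h2 = h2, h3 = h3, h4 = h4,
                        u1 = h1, u3 = h3, u4 = h4,
                        H = fi$H, g1 = fi$g1, g2 = fi$g2)
  class(out) <- c("sr_trajectory", class(out))
  attr(out, "h0") <- as_covector(h0)
  attr(out, "cut_time") <- cut_time
  out
}

integrate_normal <- function(q0, h0, times, rtol = 1e-11, atol = 1e-12) {
  y0 <- c(q0$x, q0$y, q0$theta, q0$sigma, h0$h1, h0$h2, h0$h3, h0$h4)
  sol <- deSolve::ode(y = y0, times = times, func = "sim2_normal",
                      parms = NULL, dllname = "sim2geo",
                      rtol = rtol, atol = atol, method = "lsoda",
                      maxsteps = 1e6)
  sol
}

#' Sub-Riemannian exponential map on SIM(2)
#'
#' Integrates the normal extremal flow from a base configuration (the group
#' identity by default) for an initial covector on the arc-length level set
#' `h1^2 + h3^2 + h4^2 = 1`.  Time is arc length, so `T` is also the
#' sub-Riemannian length of the returned geodesic candidate.  Conserved
#' quantities (`H`, `g1`, `g2`) are logged at every sample.
#'
#' @param h0 Initial covector (tibble or numeric length 4).
#' @param T Final arc length (>= 0).
#' @param n_samples Number of output samples (>= 2).
#' @param q0 Base configuration; defaults to the identity.
#' @param renormalize If `TRUE`, rescale `(h1, h3, h4)` onto the unit level
#'   set instead of erroring when `h0` is off it.
#' @param rtol,atol Integrator tolerances.
#' @return An `sr_trajectory` tibble with columns `t`, `x`, `y`, `theta`,
#'   `sigma`, `h1`..`h4`, extremal controls `u1`, `u3`, `u4`, and conserved
#'   `H`, `g1`, `g2`.
#' @export
#' @examples
#' exponential_map(covector(h3 = 1), T = pi, n_samples = 5)
exponential_map <- function(h0, T, n_samples = 201, q0 = sim2_identity(),
                            renormalize = FALSE, rtol = 1e-13, atol = 1e-14) {
  h0 <- as_covector(h0); q0 <- as_sim2(q0)
  stopifnot(nrow(h0) == 1, nrow(q0) == 1, T >= 0, n_samples >= 2)
  lvl <- hamiltonian_level(h0)
  if (abs(lvl - 1) > 1e-9) {
    if (!renormalize)
      stop("initial covector is off the unit level set h1^2+h3^2+h4^2 = 1 (",
           format(lvl), "); pass renormalize = TRUE to rescale", call. = FALSE)
    s <- 1 / sqrt(lvl)
    h0 <- covector(h0$h1 * s, h0$h2, h0$h3 * s, h0$h4 * s)
  }
  times <- seq(0, T, length.out = n_samples)
  if (T == 0) {
    sol <- matrix(c(0, q0$x, q0$y, q0$theta, q0$sigma,
                    h0$h1, h0$h2, h0$h3, h0$h4), nrow = 1)
    sol <- sol[rep(1, n_samples), , drop = FALSE]
    sol[, 1] <- times
  } else {
    sol <- integrate_normal(q0, h0, times, rtol, atol)
  }
  new_trajectory(sol[, 1], sol[, 2], sol[, 3], sol[, 4], sol[, 5],
                 sol[, 6], sol[, 7], sol[, 8], sol[, 9], h0 = h0)
}

# Endpoint-only integration used heavily by the shooting solver.
exp_endpoint <- function(h0, T, q0 = sim2_identity(), rtol = 1e-11,
                         atol = 1e-12) {
  if (T == 0) return(as_sim2(q0))
  sol <- integrate_normal(as_sim2(q0), as_covector(h0), c(0, T), rtol, atol)
  sim2(sol[2, 2], sol[2, 3], sol[2, 4], sol[2, 5])
}

#' Abnormal extremal trajectories
#'
#' The abnormal Pontryagin extremals are the pure scale lines
#' `x = y = theta = 0`, `sigma(t) = +/- t` (arc length parameterization).
#' They coincide with the normal extremals for `h0 = (0, 0, 0, +/-1)`, so
#' they are not strictly abnormal; the returned covector columns carry that
#' normal representative.
#'
#' @param T Arc length (>= 0).
#' @param direction `+1` (thickening) or `-1` (thinning).
#' @param n_samples Number of samples.
#' @return An `sr_trajectory` tibble.
#' @export
abnormal_trajectory <- function(T, direction = 1, n_samples = 201) {
  stopifnot(T >= 0, direction %in% c(-1, 1), n_samples >= 2)
  t <- seq(0, T, length.out = n_samples)
  z <- rep(0, n_samples)
  new_trajectory(t, z, z, z, direction * t, z, z, z, rep(direction, n_samples),
                 h0 = covector(0, 0, 0, direction))
}

#' Fiber geodesics and their cut time
#'
#' For initial covectors with `h1 = h2 = 0` and `h30^2 + h40^2 = 1` the
#' normal extremals stay in the fiber over the origin:
#' `x = y = 0`, `theta(t) = h30 t`, `sigma(t) = h40 t`.  They are length
#' minimizers up to the cut time `pi / |h30|` (infinite when `h30 = 0`):
#' beyond it the trajectory has passed the Maxwell point where it meets the
#' mirror geodesic with `h3(0) = -h30`.
#'
#' @param h30,h40 Initial orientation/scale momenta with
#'   `h30^2 + h40^2 = 1`.
#' @param T Arc length.
#' @param n_samples Number of samples.
#' @return An `sr_trajectory` tibble whose `cut_time` attribute (also
#'   available via [cut_time()]) is `pi / |h30|`, or `Inf` when `h30 = 0`.
#' @export
fiber_geodesic <- function(h30, h40, T, n_samples = 201) {
  stopifnot(abs(h30^2 + h40^2 - 1) < 1e-9, T >= 0, n_samples >= 2)
  t <- seq(0, T, length.out = n_samples)
  z <- rep(0, n_samples)
  ct <- if (h30 == 0) Inf else pi / abs(h30)
  new_trajectory(t, z, z, h30 * t, h40 * t, z, z,
                 rep(h30, n_samples), rep(h40, n_samples),
                 h0 = covector(0, 0, h30, h40), cut_time = ct)
}

#' @rdname fiber_geodesic
#' @param traj An `sr_trajectory`.
#' @export
cut_time <- function(traj) attr(traj, "cut_time")

#' Maxwell pair of mirror fiber geodesics
#'
#' The two fiber geodesics with `h3(0) = +h30` and `-h30` (same `h40`) rotate
#' in opposite senses and first meet again when their orientations coincide
#' on the circle, i.e. at wrapped angle `pi`.  The meeting time and
#' configuration are located numerically: both trajectories are integrated
#' with the full flow and the first sign change of the wrapped orientation
#' difference is bisected to the requested tolerance, then cross-checked on
#' the full configuration.
#'
#' @param h30 Nonzero orientation momentum; @param h40 scale momentum, with
#'   `h30^2 + h40^2 = 1`.
#' @param tol Bisection tolerance on the meeting time.
#' @return A list with `time` (the meeting time), `config` (the meeting
#'   configuration, a one-row tibble), `theta_abs` (wrapped `|theta|` at the
#'   meeting) and `coincidence_error` (endpoint distance between the two
#'   trajectories at the located time).
#' @export
maxwell_pair <- function(h30, h40, tol = 1e-10) {
  stopifnot(abs(h30^2 + h40^2 - 1) < 1e-9)
  if (h30 == 0)
    stop("h30 = 0: the two trajectories coincide and there is no Maxwell point",
         call. = FALSE)
  hp <- covector(0, 0, abs(h30), h40)
  hm <- covector(0, 0, -abs(h30), h40)
  ep <- function(t) exp_endpoint(hp, t)
  em <- function(t) exp_endpoint(hm, t)
  # signed wrapped orientation difference between the two trajectories
  g <- function(t) wrap_angle(ep(t)$theta - em(t)$theta)
  t_hi <- 1.25 * pi / abs(h30)
  ts <- seq(1e-3, t_hi, length.out = 64)
  gs <- vapply(ts, g, numeric(1))
  flip <- which(gs[-1] * gs[-length(gs)] <= 0 & abs(diff(gs)) < pi)[1]
  if (is.na(flip)) stop("no coincidence found in the search window", call. = FALSE)
  lo <- ts[flip]; hi <- ts[flip + 1]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (g(lo) * g(mid) <= 0) hi <- mid else lo <- mid
  }
  tm <- (lo + hi) / 2
  qp <- ep(tm); qm <- em(tm)
  list(time = tm,
       config = qp,
       theta_abs = abs(wrap_angle(qp$theta)),
       coincidence_error = endpoint_error(qp, qm))
}

#' Poisson bivector of the vertical coordinates
#'
#' The Poisson brackets of the frame momenta mirror the Lie brackets of the
#' frame: the nonzero ones are `{h1,h3} = -h2`, `{h1,h4} = -h1`,
#' `{h2,h3} = h1`, `{h2,h4} = -h2`.  The resulting antisymmetric 4x4 matrix
#' has determinant `(h1^2 + h2^2)^2`, so the coadjoint orbit through `h` is
#' zero-dimensional when `h1 = h2 = 0` and four-dimensional otherwise.
#'
#' @param h A covector.
#' @return A list with the matrix `P`, its `det`, and its `rank`.
#' @export
poisson_matrix <- function(h) {
  h <- as_covector(h)
  stopifnot(nrow(h) == 1)
  P <- matrix(0, 4, 4)
  P[1, 3] <- -h$h2; P[1, 4] <- -h$h1
  P[2, 3] <- h$h1;  P[2, 4] <- -h$h2
  P[lower.tri(P)] <- -t(P)[lower.tri(P)]
  list(P = P, det = det(P),
       rank = qr(P, tol = 1e-12)$rank)
}

#' Asymptotics of the vertical subsystem
#'
#' Integrates only the vertical momenta equations for a unit initial covector
#' and reports the tail behavior: for `h1^2 + h2^2 > 0` and `h4(0) < 0` the
#' in-plane momenta decay to zero and `(h3, h4)` converge to a point on the
#' unit circle, while `h4` is non-increasing along every extremal
#' (`h4dot = -h1^2`).  The regime `h4(0) >= 0` is reported as a diagnostic
#' only (conjectured, not proven).
#'
#' @param h0 Unit initial covector.
#' @param T_long Final time (>= 10).
#' @param n_samples Samples used for the monotonicity scan.
#' @return A list with `h_tail` (covector at `T_long`), `abs_h1`, `abs_h2`,
#'   `h3sq_plus_h4sq`, `h4_nonincreasing` (logical, checked on the sample
#'   grid with tolerance 1e-10) and the sampled `trajectory` tibble.
#' @export
vertical_tail <- function(h0, T_long = 50, n_samples = 2001) {
  h0 <- as_covector(h0)
  stopifnot(nrow(h0) == 1, T_long >= 10)
  if (abs(hamiltonian_level(h0) - 1) > 1e-9)
    stop("h0 must lie on the unit level set", call. = FALSE)
  times <- seq(0, T_long, length.out = n_samples)
  sol <- deSolve::ode(y = c(h0$h1, h0$h2, h0$h3, h0$h4), times = times,
                      func = "sim2_vertical", parms = NULL,
                      dllname = "sim2geo", rtol = 1e-13, atol = 1e-14,
                      method = "lsoda", maxsteps = 1e6)
  tail_h <- covector(sol[n_samples, 2], sol[n_samples, 3],
                     sol[n_samples, 4], sol[n_samples, 5])
  traj <- tibble::tibble(t = sol[, 1], h1 = sol[, 2], h2 = sol[, 3],
                         h3 = sol[, 4], h4 = sol[, 5])
  list(h_tail = tail_h,
       abs_h1 = abs(tail_h$h1), abs_h2 = abs(tail_h$h2),
       h3sq_plus_h4sq = tail_h$h3^2 + tail_h$h4^2,
       h4_nonincreasing = all(diff(traj$h4) <= 1e-10),
       trajectory = traj)
}

#' First return time of an extremal to a configuration
#'
#' Scans the endpoint distance between the flowing extremal and a target
#' configuration on a coarse grid, then refines the first local minimum by
#' golden-section search on fresh integrations.  Used e.g. to locate the
#' `2*pi` period of the pure rotation extremal `h0 = (0, 0, 1, 0)` blindly
#' from the numerical flow.
#'
#' @param h0 Unit initial covector.
#' @param q_target Configuration to return to (identity by default).
#' @param t_max Search horizon; @param coarse_dt scan step.
#' @param match_tol Endpoint error below which a minimum counts as a return.
#' @return A list with `time` and `error` (`time = NA` if no return found).
#' @export
first_return_time <- function(h0, q_target = sim2_identity(), t_max = 10,
                              coarse_dt = 0.05, match_tol = 1e-4) {
  h0 <- as_covector(h0); q_target <- as_sim2(q_target)
  f <- function(t) endpoint_error(exp_endpoint(h0, t), q_target)
  ts <- seq(coarse_dt, t_max, by = coarse_dt)
  fs <- vapply(ts, f, numeric(1))
  n <- length(ts)
  for (i in seq(2, n - 1)) {
    if (fs[i] <= fs[i - 1] && fs[i] <= fs[i + 1] && fs[i] < 10 * coarse_dt) {
      opt <- stats::optimize(f, c(ts[i - 1], ts[i + 1]), tol = 1e-12)
      if (opt$objective < match_tol)
        return(list(time = opt$minimum, error = opt$objective))
    }
  }
  list(time = NA_real_, error = min(fs))
}
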