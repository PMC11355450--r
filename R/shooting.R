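#' Endpoint discrepancy between two configurations
#'
#' The residual metric used by the shooting solver:
#' `sqrt(dx^2 + dy^2 + wrap(dtheta)^2 + dsigma^2)` with the orientation
#' difference wrapped to `(-pi, pi]`.  It vanishes exactly when the two
#' configurations coincide on SIM(2) (orientation modulo full turns) and is
#' symmetric in its arguments.  Vectorized over rows.
#'
#' @param q,q_target Configuration tibbles (rows recycled).
#' @return Numeric vector of discrepancies.
#' @export
endpoint_error <- function(q, q_target) {
  q <- as_sim2(q); q_target <- as_sim2(q_target)
  sqrt((q$x - q_target$x)^2 + (q$y - q_target$y)^2 +
       wrap_angle(q$theta - q_target$theta)^2 + (q$sigma - q_target$sigma)^2)
}

#' Certified lower bound on the sub-Riemannian distance
#'
#' Along any unit-speed horizontal curve `|sigmadot| <= 1` and
#' `|thetadot| <= 1`, so the arc length needed to change orientation or
#' log-thickness is at least the coordinate gap:
#' `d(a, b) >= max(|wrap(dtheta)|, |dsigma|)`.  Both differences are
#' left-invariant, so the bound is computed directly from coordinate
#' differences.  It is tight for pure fiber motions.  Vectorized over rows.
#'
#' @param a,b Configuration tibbles.
#' @return Numeric vector of lower bounds.
#' @export
sr_distance_lower_bound <- function(a, b) {
  a <- as_sim2(a); b <- as_sim2(b)
  pmax(abs(wrap_angle(b$theta - a$theta)), abs(b$sigma - a$sigma))
}

# Deterministic quasi-uniform directions on the sphere (Fibonacci lattice),
# used as initial (h1, h3, h4) shooting directions.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (1 + sqrt(5)) * i
  cbind(r * cos(phi), r * sin(phi), z)
}

# Total rotation of the orientation along a trajectory, used to discard
# candidates that have wound past a full turn (heuristically beyond any
# Maxwell point of the S^1 periodicity type).
total_rotation <- function(h0, T, n = 65) {
  tr <- exponential_map(h0, T, n_samples = n, rtol = 1e-8, atol = 1e-9)
  dt <- T / (n - 1)
  sum(abs(tr$h3)) * dt
}

#' Solve the geodesic boundary-value problem by shooting
#'
#' Searches for an initial covector on the unit level set and an arc length
#' `T` whose exponential map reaches `q_target`, by damped least-squares
#' (Levenberg-Marquardt) on the endpoint residual from multiple deterministic
#' starts.  The initial momentum is parameterized by spherical angles of
#' `(h1, h3, h4)` plus a free `h2`, and `T` by its logarithm.  When the
#' target sits in the fiber over the origin (`x = y = 0`) the closed-form
#' fiber/scale geodesic supplies an exact candidate.  Among converged
#' candidates (residual below `tol`), those whose total orientation rotation
#' exceeds `2*pi` are discarded (past a Maxwell-type point on the fiber-case
#' analogy) and the smallest-`T` candidate is returned as the minimal
#' geodesic candidate; global optimality is approximated, not certified.
#'
#' @param q_target Target configuration (one row); the identity returns the
#'   trivial `T = 0` result.
#' @param tol Convergence threshold on the endpoint residual.
#' @param n_starts Number of quasi-uniform sphere starts.
#' @param t_cap Upper bound used to reject runaway candidates.
#' @param n_polish Number of screened starts refined by Levenberg-Marquardt
#'   (all starts receive a cheap residual screen first).
#' @param early_stop Stop scanning starts once a converged candidate is
#'   provably within `1e-6` of the certified lower bound.
#' @return An object of class `sr_shoot`: a list with `h0`, `T`, `residual`,
#'   `converged`, `trajectory` (an `sr_trajectory`), `n_starts_used`,
#'   `target` and the per-candidate table `candidates`.  See
#'   [tidy.sr_shoot()] and [glance.sr_shoot()].
#' @export
#' @examples
#' \donttest{
#' shoot(sim2(0, 0, pi / 2, 0))$T   # pi/2, a pure rotation geodesic
#' }
shoot <- function(q_target, tol = 1e-6, n_starts = 32, t_cap = 25,
                  n_polish = 8, early_stop = TRUE) {
  q_target <- as_sim2(q_target)
  stopifnot(nrow(q_target) == 1)
  lb <- sr_distance_lower_bound(sim2_identity(), q_target)

  if (endpoint_error(q_target, sim2_identity()) < .Machine$double.eps^0.5) {
    tr <- exponential_map(covector(0, 0, 0, 1), 0, n_samples = 2)
    return(new_sr_shoot(covector(0, 0, 0, 1), 0, 0, TRUE, tr, 0, q_target,
                        tibble::tibble()))
  }

  par_cov <- function(par)
    covector(cos(par[2]) * cos(par[1]), par[3],
             cos(par[2]) * sin(par[1]), sin(par[2]))
  residual_fun <- function(par, rtol = 1e-9, atol = 1e-10) {
    T <- exp(par[4])
    if (!is.finite(T) || T > t_cap) return(rep(1e3, 4))
    qe <- exp_endpoint(par_cov(par), T, rtol = rtol, atol = atol)
    c(qe$x - q_target$x, qe$y - q_target$y,
      wrap_angle(qe$theta - q_target$theta), qe$sigma - q_target$sigma)
  }

  starts <- list()
  # closed-form candidate for fiber targets: theta/sigma line
  if (abs(q_target$x) < 1e-9 && abs(q_target$y) < 1e-9) {
    dth <- wrap_angle(q_target$theta); dsg <- q_target$sigma
    Tf <- sqrt(dth^2 + dsg^2)
    starts[[length(starts) + 1]] <-
      c(atan2(dth / Tf, 0), asin(max(-1, min(1, dsg / Tf))), 0, log(Tf))
  }
  d0 <- sqrt(q_target$x^2 + q_target$y^2)
  # the (x, sigma) subsystem is a hyperbolic half-plane (y = e^sigma), which
  # gives a closed-form candidate for spatially distant targets: geodesics
  # thicken mid-way because travel is cheaper at larger scales
  es <- exp(q_target$sigma)
  d_hyp <- acosh(1 + (d0^2 + (es - 1)^2) / (2 * es))
  T0 <- max(lb, min(d0, d_hyp), 0.2)
  if (d0 > 1e-9) {
    beta <- atan2(q_target$y, q_target$x)
    cc <- (d0^2 + es^2 - 1) / (2 * d0)
    h1g <- 1 / sqrt(1 + cc^2); h4g <- cc / sqrt(1 + cc^2)
    h3g <- 2 * wrap_angle(beta) / max(d_hyp, 0.2)
    nrm <- sqrt(h1g^2 + h3g^2 + h4g^2)
    starts[[length(starts) + 1]] <-
      c(atan2(h3g / nrm, h1g / nrm), asin(max(-1, min(1, h4g / nrm))), 0,
        log(max(d_hyp, 0.1)))
  }
  dirs <- fibonacci_sphere(n_starts)
  for (k in seq_len(n_starts))
    starts[[length(starts) + 1]] <-
      c(atan2(dirs[k, 2], dirs[k, 1]), asin(dirs[k, 3]), 0, log(T0))

  # cheap screen: one endpoint integration per start, then polish the best
  screen <- vapply(starts, function(st)
    sqrt(sum(residual_fun(st, rtol = 1e-8, atol = 1e-9)^2)), numeric(1))
  order_idx <- order(screen)
  polish_idx <- order_idx[seq_len(min(n_polish, length(starts)))]

  cand <- list()
  used <- 0
  for (si in polish_idx) {
    used <- used + 1
    fit <- try(suppressWarnings(minpack.lm::nls.lm(
      par = starts[[si]], fn = residual_fun,
      control = minpack.lm::nls.lm.control(maxiter = 40, ftol = 1e-14,
                                           ptol = 1e-12))), silent = TRUE)
    if (inherits(fit, "try-error")) next
    par <- fit$par
    # verify at tight integrator tolerance
    res <- sqrt(sum(residual_fun(par, rtol = 1e-11, atol = 1e-12)^2))
    T <- exp(par[4])
    h0 <- par_cov(par)
    ok <- is.finite(res) && res < tol && T <= t_cap
    rot <- if (ok) total_rotation(h0, T) else NA_real_
    keep <- ok && rot <= 2 * pi + 1e-6
    cand[[length(cand) + 1]] <-
      tibble::tibble(h1 = unname(h0$h1), h2 = unname(h0$h2),
                     h3 = unname(h0$h3), h4 = unname(h0$h4),
                     T = unname(T), residual = unname(res), converged = ok,
                     total_rotation = unname(rot), kept = keep)
    # provably minimal: no geodesic can beat the certified lower bound
    if (early_stop && keep && T <= lb * (1 + 1e-6) + 1e-6) break
    # pragmatic stop: a converged candidate plus a few alternatives scanned
    if (early_stop && used >= 4 &&
        any(vapply(cand, function(cc) cc$kept, logical(1)))) break
  }
  cand <- dplyr::bind_rows(cand)
  kept <- dplyr::filter(cand, .data$kept)
  if (nrow(kept) == 0) {
    ibest <- which.min(cand$residual)
    h0 <- covector(cand$h1[ibest], cand$h2[ibest], cand$h3[ibest],
                   cand$h4[ibest])
    tr <- exponential_map(h0, cand$T[ibest], renormalize = TRUE)
    return(new_sr_shoot(h0, cand$T[ibest], cand$residual[ibest], FALSE, tr,
                        used, q_target, cand))
  }
  ibest <- which.min(kept$T)
  h0 <- covector(kept$h1[ibest], kept$h2[ibest], kept$h3[ibest],
                 kept$h4[ibest])
  tr <- exponential_map(h0, kept$T[ibest], renormalize = TRUE)
  new_sr_shoot(h0, kept$T[ibest], kept$residual[ibest], TRUE, tr, used,
               q_target, cand)
}

new_sr_shoot <- function(h0, T, residual, converged, trajectory,
                         n_starts_used, target, candidates) {
  T <- unname(T); residual <- unname(residual)
  structure(list(h0 = h0, T = T, residual = residual, converged = converged,
                 trajectory = trajectory, n_starts_used = n_starts_used,
                 target = target, candidates = candidates),
            class = "sr_shoot")
}

#' @export
print.sr_shoot <- function(x, ...) {
  cat("<sr_shoot> ", if (x$converged) "converged" else "NOT converged",
      sprintf(": T = %.8g, residual = %.3g (%d starts)\n",
              x$T, x$residual, x$n_starts_used))
  cat("  h0 = (", paste(sprintf("%.6f", unlist(x$h0)), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Sub-Riemannian distance on SIM(2)
#'
#' The distance is the arc length of the best converged shooting candidate
#' (unit-speed parameterization makes time, length and distance coincide).
#' With a single argument it is the distance from the identity; with two, the
#' relative configuration `a^{-1} b` is shot, which realizes left invariance
#' `d(a, b) = d(Id, a^{-1} b)` by construction.
#'
#' @param a Target (or first) configuration.
#' @param b Optional second configuration.
#' @param ... Passed to [shoot()].
#' @return Distance estimate (scalar).  `NA` with a warning when the solver
#'   fails to converge.
#' @export
sr_distance <- function(a, b = NULL, ...) {
  target <- if (is.null(b)) as_sim2(a)
            else sim2_multiply(sim2_inverse(a), b)
  s <- shoot(target, ...)
  if (!s$converged) {
    warning("shooting did not converge; returning NA")
    return(NA_real_)
  }
  s$T
}
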