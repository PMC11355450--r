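---
title: "Contour completion by sub-Riemannian geodesics on SIM(2)"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contour completion by sub-Riemannian geodesics on SIM(2)}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sim2geo)
```

## The model

Primary visual cortex cells respond not only to the retinal position of a
stimulus but also to its orientation and — for cells of different receptive
field sizes — to its scale, i.e. the local thickness of a contour.  This
package models the configuration space of such cells as the group of
orientation-preserving similarity transformations of the plane,

$$\mathrm{SIM}(2) \ni q = (x, y, \theta, \sigma),$$

with $(x,y)$ the retinal position, $\theta \in S^1$ the contour orientation
and $\sigma$ the log-thickness ($\kappa = e^\sigma$ is the physical
thickness).  Long-range neural connections are admissible only along a rank-3
subbundle of the tangent bundle, spanned by the left-invariant fields

$$X_1 = e^\sigma(\cos\theta\,\partial_x + \sin\theta\,\partial_y), \quad
  X_3 = \partial_\theta, \quad X_4 = \partial_\sigma,$$

equivalently the kernel of the contact form
$\omega = e^{-\sigma}(-\sin\theta\,dx + \cos\theta\,dy)$: a contour may
advance along its own direction, turn, or change thickness, but not slide
sideways.  The energy of a connection is the sub-Riemannian length

$$\ell(\gamma) = \int_0^T \sqrt{u_1^2 + \alpha^2 u_3^2 + \beta^2 u_4^2}\,dt,$$

and a hidden contour fragment is reconstructed as the length minimizer
between the boundary configurations.  The package carries general metric
weights $\alpha, \beta$ in `horizontal_speed()` but implements the geodesic
flow for the model case $\alpha = \beta = 1$; non-unit weights in the flow
are rejected rather than silently approximated.

Under arc-length parameterization the Pontryagin maximum principle gives the
normal extremal system in left-invariant momenta $h = (h_1, h_2, h_3, h_4)$:

$$\dot x = h_1 e^\sigma \cos\theta,\;
  \dot y = h_1 e^\sigma \sin\theta,\;
  \dot\theta = h_3,\;
  \dot\sigma = h_4,$$
$$\dot h_1 = h_3 h_2 + h_4 h_1,\;
  \dot h_2 = -h_3 h_1 + h_4 h_2,\;
  \dot h_3 = -h_1 h_2,\;
  \dot h_4 = -h_1^2,$$

with conserved quantities $H = h_1^2 + h_3^2 + h_4^2$ (fixed to 1) and
$g_1, g_2$ — the constant chart momenta $p_1, p_2$.  Abnormal extremals are
the pure scale lines $\sigma(t) = \pm t$ and coincide with normal extremals,
so nothing is lost by integrating the normal system only.

A sign convention worth recording: with $h_i = \langle p, X_i\rangle$ the
in-plane momenta satisfy $h_2 = e^\sigma(-p_1\sin\theta + p_2\cos\theta)$.
This is the only convention under which the vertical equations above, the
conservation of $g_1 = p_1$, $g_2 = p_2$, and the bracket table are
simultaneously consistent, and it is the one implemented and tested
(`chart_momentum()` / `frame_momentum()`).

## Numerical choices

**Integration.** The flow is integrated by `deSolve`'s `lsoda` with a
compiled right-hand side.  Default tolerances are `rtol = 1e-13`,
`atol = 1e-14`: the conserved $g_1, g_2$ carry a factor $e^{-\sigma}$, which
amplifies local error by up to $e^{10}$ on the horizons ($T = 10$) used by
the conservation checks, and the looser classical choice `1e-11/1e-12`
measurably fails the `1e-8` relative-drift bound that the test suite
enforces.  Over much longer horizons ($T = 50$ with $h_4 < 0$) the same
amplification grows like $e^{T}$ and no practical tolerance maintains
`1e-8` relative drift in $g_1, g_2$; accuracy there is asserted on the
vertical subsystem, which is free of the amplification.  The shooting
solver's inner iterations use `1e-9/1e-10` for speed and re-verify every
converged candidate at `1e-11/1e-12`.

**Event location.** Return times and Maxwell meeting times are found
blind from the numerics: a coarse scan brackets the event, then
golden-section refinement (returns) or bisection on the signed wrapped
orientation difference (meetings) narrows it to `1e-10`–`1e-12`.

**Shooting.** `shoot()` parameterizes the unknown initial covector by
spherical angles of $(h_1, h_3, h_4)$ plus a free $h_2$, and the unknown
arc length by its logarithm.  Thirty-two deterministic Fibonacci-sphere
starts plus two closed-form candidates are screened by a single cheap
integration each, and the most promising are polished by
Levenberg–Marquardt (`minpack.lm`).  The closed-form candidates matter:
targets in the fiber over the origin are hit exactly by the
$\theta$/$\sigma$-line geodesics, and spatially distant targets by the
geodesics of the $(x, e^\sigma)$ hyperbolic half-plane — the $(x,\sigma)$
subsystem of the flow, in which travel is cheaper at larger scales.
Candidates whose total orientation rotation $\int |h_3|\,dt$ exceeds $2\pi$
are discarded as necessarily past a Maxwell-type point (a heuristic modeled
on the fiber case, where optimality is provably lost at wrapped angle
$\pi$); among the survivors the smallest arc length wins.  The solver
therefore returns candidate minimizers — global optimality on SIM(2) has no
known synthesis and is not certified.

**Distance.** `sr_distance(a, b)` shoots the relative configuration
$a^{-1}b$, which makes left invariance exact by construction.
`sr_distance_lower_bound()` is the certified bound
$\max(|\Delta\sigma|, |\mathrm{wrap}(\Delta\theta)|)$ — along unit-speed
horizontal curves $|\dot\sigma| \le 1$ and $|\dot\theta| \le 1$, while no
analogous spatial bound holds because planar speed scales with $e^\sigma$.

## The Gabor lifting

Images are lifted to SIM(2) by a two-parameter bank of receptive profiles
derived from the even mother filter
$G(x, y) = e^{-(x^2+y^2)}\cos 2y$ by rotation and dilation (with the
$e^{-2\sigma}$ dilation prefactor).  Fiberwise maxima of the absolute
response select the orientation and scale engrafted at each retinal point.
Decisions the formulas leave open, resolved here once:

* **Magnitude.** The argmax is over $|O|$: the even filter flips sign with
  contrast polarity, which carries no geometric information.
* **Half-circle orientation grid.** The even profile makes responses
  $\pi$-periodic in $\theta$, so the bank samples $[0, \pi)$ (default 16
  orientations) and the antipodal direction is resolved during endpoint
  pairing by orienting each endpoint into the damaged region.
* **Scale grid and units.** Default 8 log-scales uniform on $[-1, 1.8]$,
  the upper end matching the grouping scene's $\sigma$ range; `pixel_size`
  maps pixels to retinal units (default 1).  Kernels are truncated at 3
  Gaussian radii, where the envelope is below $1.3\times10^{-4}$.
* **Pixel integration.** Kernels are integrated over pixel areas (midpoint
  supersampling) rather than point-sampled.  Point sampling aliases
  sub-pixel scales so badly that the $e^{-2\sigma}$ prefactor wins every
  argmax; with pixel integration the response of an aligned bar of width
  $w$ peaks at $\bar\sigma = \ln w - \ln(\pi/2)$, about 1.37 times the
  small-scale plateau, which is what the selection tests verify.  Widths
  below about 3 pixels sit at the sampling limit and are excluded from the
  fixtures' operating range.
* **Calibration.** The bank's $\bar\sigma$ is pinned to physical stroke
  width once, on a reference bar (`calibrate_bank()`), and the offset is
  stored with the bank; completion converts selected scales to rendered
  widths through it.
* **Sub-grid refinement.** `select_orientation_scale(refine = TRUE)`
  sharpens the grid argmax by separable 3-point parabolic interpolation
  (periodic in $\theta$, clamped in $\sigma$), so completion widths are not
  quantized to the scale grid.  The unrefined path keeps the documented
  tie-break (first grid pair lexicographically) and flags
  (`tie` / `no_response`).
* **Endpoint probing.** Filters centered at a cut face see the contour
  termination, not the contour: on a severed bar the selected orientation
  at the face is perpendicular to the true one.  Boundary configurations
  are therefore probed on a ring standing off the damage mask, and
  `complete_contours()` grows that offset iteratively to about one
  estimated contour width, where selection has stabilized.

## What the applications show

**Association field.** Ten geodesics with $h_2(0) = h_4(0) = 0$ and
$(h_1(0), h_3(0))$ on a printed two-decimal fan (renormalized onto
$H = 1$) are integrated to a long horizon.  Two properties are asserted:
exact $y \mapsto -y$ mirror symmetry (the flow commutes with
$(\theta, y, h_2, h_3) \to -(\theta, y, h_2, h_3)$), and bounded spatial
propagation — $\dot h_4 = -h_1^2$ drives $\sigma$ down, the planar speed
$h_1 e^\sigma$ decays, and the projections stop advancing.  The fan's
finite reach is the model's account of why contour association weakens
with distance.

**Perceptual grouping.** Foreground elements are stepped along three
seeded geodesic segments at arc-length spacing $d = 0.1$ — unit speed makes
consecutive sub-Riemannian distances equal $d$ on minimizing sub-arcs,
which is spot-checked by shooting.  The background grid's orientations and
scales ($\sigma \in [0, 1.8]$) are rejection-sampled until every pair
clears the certified lower bound $0.18$; the bound depends only on
$(\theta, \sigma)$ gaps, so a feasibility check compares the grid size
against the $L^\infty$ packing capacity of the $(\theta, \sigma)$ strip
and refuses impossible configurations.  The three segments, the grid
geometry and the glyphs are not pinned by anything quantitative; they are
seeded defaults chosen for a legible scene.

**Completion.** The workflow is: extract boundary configurations, orient
them into the mask, pair greedily by ascending shooting distance, connect
each pair by a geodesic, and stamp discs of diameter $e^{\sigma(t)}$
(through the bank calibration) along it, writing only inside the mask —
pixels outside are returned bit-identical.  One genuine model behavior
shapes the tests: between two configurations of equal thickness the
minimizer *swells* mid-gap (the $(x, e^\sigma)$ half-plane geodesic is a
semicircle), because travel is cheaper at larger scales.  For a mask that
fully severs a bar the swell always overshoots, so "restored width is
monotone across the gap" is unattainable as stated for tapered bars; the
suite asserts the attainable versions — monotone $\sigma$ when the scale
change dominates the spatial gap ($\Delta x^2 \le e^{2\Delta\sigma} - 1$
in relative coordinates), and net thickening with an overshoot bounded by
a factor 2 through the full pipeline.  The straight-bar IoU check uses a
bar nearly as wide as the damage disc, where the restored stroke fills the
mask's bar corridor and the comparison is meaningful at pixel resolution.

## The synthetic generator

`make_curve_image()` rasterizes polyline strokes with linearly
interpolated width using coverage (area-sampled) edges, so the rasterized
mass of a width-$w$ stroke equals $w$ — binary inclusion of pixel centers
would inflate every stroke by about one pixel and bias the scale ground
truth.  It returns per-arc ground truth $(x, y, \theta, \ln w)$, is
deterministic under its seed (including optional additive noise, clipped
at zero), and `corrupt_with_disc()` produces the damage mask and the
untouched complement.  What it emulates is the geometry the model is
about — position, orientation, thickness of smooth strokes; what it does
not emulate is everything that makes real retinal imagery hard: texture,
contrast variation, branching vessels, curvature beyond piecewise-linear,
sensor noise statistics.  Passing tests on these fixtures validates the
geometry pipeline, not clinical performance.

## Problem sizes and limitations

The test suite runs the conservation sweep on 100 seeded unit covectors at
$T = 10$, shooting recovery on 50 seeded targets with $T^* \le 2$, and
completion on $61 \times 61$ canvases with 12–14 scale channels; these
sizes keep the full suite within a few minutes on one core while leaving
the tolerances honest.  Known limitations: no cut-locus computation beyond
the fiber case (shooting returns candidates, not certified minimizers);
the geodesic flow is implemented for $\alpha = \beta = 1$ only; the
lifting assumes contours at least ~3 pixels wide; Liouville integrability
of the flow is left open, so the package treats it purely numerically —
the conjectured asymptotics for $h_4(0) \ge 0$ are reported by
`vertical_tail()` as diagnostics, never asserted.
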