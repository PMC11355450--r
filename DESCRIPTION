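Package: sim2geo
Title: Sub-Riemannian Geodesics on the Planar Similarity Group for Contour Completion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models long-range contour integration in the primary visual cortex
    as sub-Riemannian geodesics on SIM(2), the group of orientation-preserving
    similarity transformations of the plane (positions, orientations and
    contour thicknesses).  Provides the group structure and left-invariant
    frame, a two-parameter Gabor filter bank that lifts grayscale images to an
    orientation-scale score, the Pontryagin extremal flow with its closed-form
    special geodesics and conserved quantities, a multi-start shooting solver
    for the geodesic boundary-value problem, and simulations of the
    association field, sub-Riemannian perceptual grouping and thickness-aware
    contour inpainting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
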