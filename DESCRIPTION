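Package: shapecurv
Title: Hierarchical Curvature-Based Representation of 2D Shape
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A five-layer feedforward model of two-dimensional shape
    representation in the ventral visual stream. Oriented
    difference-of-Gaussians simple cells are pooled into complex cells;
    endstopped operators built from one excitatory simple unit and two
    displaced inhibitory complex units discriminate the degree and the
    sign of local contour curvature; their convergence yields an
    eight-class signed local-curvature map; and shape-selective units read
    that map out over polar (radial by angular) position bins with
    Gaussian position tolerance, giving a curvature-by-parts shape code.
    Includes a parametric generator for contour stimuli (bars, circular
    arcs, and closed shapes built from convex and concave boundary
    elements), tuning-curve and response-profile tooling, and machinery
    for comparing normalized model responses against external reference
    responses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    EBImage,
    pracma,
    testthat (>= 3.0.0)
LinkingTo: Rcpp
Config/testthat/edition: 3
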