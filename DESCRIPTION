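Package: osteomap
Title: Non-Linear Osteometric Modeling of Longitudinal Bone Surface Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying continuous three-dimensional morphological
    change of a growing bone from a time-ordered series of triangulated
    surface meshes. Establishes per-vertex correspondence between consecutive
    meshes by maximizing a local neighborhood correlation under a rigid
    constraint (iterative closest point pre-alignment plus per-vertex Kabsch
    refinement), converts tracked inter-vertex distances into normalized
    monthly change rates via least-squares cubic splines, decomposes rates
    into anatomical direction components, summarises them over anatomical
    regions, and validates propagated landmark positions and inter-landmark
    rates against a gold standard by RMSE. Includes readers and writers for
    PLY, STL and OBJ surface meshes, quadric edge-collapse decimation, a
    vertex-count sensitivity scan, color-map mesh export, and a synthetic
    generator of mandible-like growing mesh series with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    stats,
    splines,
    utils,
    tools,
    grDevices,
    generics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
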