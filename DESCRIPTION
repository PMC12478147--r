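Package: morphoring
Title: Boundary-Driven Ring Morphogenesis: Constrained Elastica Models and
    Contour Kinematics for the Drosophila Hindgut Primordium
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models and quantifies the passive, boundary-driven deformation of
    ring-shaped embryonic tissues, using the Drosophila hindgut primordium as
    the reference system.  Solves the constrained planar elastica boundary-value
    problem (bending-energy minimization under inextensibility, enclosed-area
    and anteroposterior-diameter constraints), enumerates solution branches and
    builds the symmetry-breaking phase diagram; minimizes ring bending energy
    on spheres and ellipsoids with Fourier-parameterized closed curves to study
    curvature-driven orientation selection and genetic-perturbation scenarios;
    turns long-format nuclear track tables into deforming closed contours and
    shape-metric time series (length, enclosed area, roundness, axis lengths,
    intercontour distances); implements the coupled-ring offset-curve model;
    and generates synthetic embryo track tables with exact ground truth so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    deSolve,
    Matrix,
    pracma,
    dplyr,
    tibble,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
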