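Package: celldeform
Title: Phenomenological Cell and Nucleus Deformation During Confined Migration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of a deformable cell whose membrane and
    nucleus are discretised as coupled node rings with spring-like shape
    memory. Cells drift up the gradient of a chemoattractant represented by
    Green's fundamental solutions of the diffusion equation, undergo random
    motility modelled as a Wiener process, and interact with rigid obstacles
    (discs, walls and trigonometric rough channels) through tangential
    projection of their displacements. Time stepping uses an
    implicit-explicit (IMEX) Euler scheme. The package includes transit-time
    (penetration) statistics for cells squeezing through capillary-scale
    channels, Monte Carlo uncertainty quantification over model parameters
    with Pearson correlation screens, and Richardson-based error budgets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    graphics,
    parallel,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
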