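Package: cellcontour
Title: Contour Dynamics of Cellular Shapes Driven by Curved Membrane
    Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulator for the coupled dynamics of a one-dimensional cell
    membrane contour and a curvature-sensing membrane protein field.
    Protrusive forces from actin polymerization and from adhesion-induced
    tension reduction are recruited by convex membrane proteins, driving
    spontaneous protrusion formation, coalescence coarsening, and distinct
    adhesion-driven (tent/droplet) versus actin-driven (fan/crescent)
    steady-state morphologies.  Includes linear stability analysis
    (dispersion relations, phase diagram, critical boundaries), an explicit
    Euler contour integrator with mass-conserving re-discretization, and
    quantitative shape observables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
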