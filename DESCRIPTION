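Package: shiftnet
Title: Optimized Multi-Species Monitoring Networks for Climate-Driven Range Shifts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to design multi-species monitoring networks optimized to
    detect climate-driven range shifts. Continuous habitat-suitability surfaces
    are thresholded at the 10th percentile of training-presence values, cells
    are classified into likely gain, maintain or loss of climatic suitability
    between present and future projections, and monitoring stations are placed
    by solving a stratified minimum-set representation problem with a
    simulated-annealing solver under Marxan semantics (feature penalties,
    lock-in for nested network expansion, cost thresholds), together with an
    exact branch-and-bound oracle for small instances, evaluation of
    distribution-only comparison networks, and niche-comparison statistics
    (Schoener's D, Levins' niche breadth, cell agreement). A seeded synthetic
    landscape generator emulates the spatial structure the analysis assumes so
    the full pipeline is testable without external rasters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
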