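Package: pulsetim
Title: Pulsed Immunotherapy Dynamics in a Tumor-Immune-Cytokine Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing a three-compartment ordinary differential
    equation model of tumor cells, CD4+ T cells and an antitumor cytokine
    (IL-4), with and without periodically pulsed immunotherapy. Provides the
    autonomous vector field, closed-form equilibria and slow-manifold
    reduction, analytic stability thresholds (transcritical antigenicity
    threshold, Hopf condition of the reduced system, per-pulse cytokine dose
    threshold for tumor clearance), an impulsive simulator with a
    stroboscopic Poincare map, Floquet multipliers via variational
    equations, and numerical bifurcation machinery (fold, transcritical,
    Hopf and Neimark-Sacker location, one- and two-parameter diagrams,
    three-parameter bifurcation surfaces).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    tibble,
    dplyr,
    purrr,
    tidyr,
    ggplot2,
    rlang,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
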