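Package: anchortrap
Title: Anchor-Mediated Trapping of Nanoparticulates in Biogels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Stochastic and analytic models of third-party molecular anchors
    (for example IgG antibodies) that crosslink diffusing nanoparticulates to a
    biopolymer matrix. Implements the exact (n, s) continuous-time Markov chain
    of the anchor binding network, its quasi-steady-state reduction to an
    effective diffusivity, Gillespie stochastic simulation with a time-fraction
    diffusivity estimator, first-passage ("absorption") probability across a gel
    layer, matrix-saturation and multi-species capacity theory, finite-difference
    sensitivity analysis, and a multiple-particle-tracking pipeline
    (time-averaged and geometric ensemble mean squared displacements, effective
    diffusivities, anomalous exponents, mobile-fraction classification) with a
    synthetic switching-diffusion trajectory generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
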