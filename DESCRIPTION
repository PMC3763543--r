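Package: polshuttle
Title: Single-Molecule Kinetics of DNA Polymerase Binding Orientations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis of single-molecule fluorescence
    trajectories of DNA polymerase binding to primer-template DNA.
    Continuous-time Markov chain simulation of multi-state binding
    schemes (pol, exo and intermediate sites), camera-frame integration
    of donor/acceptor FRET and protein-induced fluorescence enhancement
    (PIFE) signals with Gaussian detection noise and photobleaching,
    Gaussian-mixture population analysis, censored-exponential dwell-time
    rate estimation with free-energy differences, Gaussian-emission
    hidden Markov model trace idealization with transition density
    plots, and pause-length-distribution model comparison to infer
    dissociation pathway splits.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils,
    Rcpp,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
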