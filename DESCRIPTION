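Package: triplexr
Title: Identification and Kinetic Analysis of Cooperative microRNA Pairs
    and Their RNA Triplexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting and characterising RNA triplexes, i.e.
    a target mRNA bound simultaneously by two cooperating microRNAs at
    neighbouring 3' UTR sites. Starting from miRanda-style target-site
    tables and sequences, the package pairs sites under the 13-35 nt
    seed-distance constraint, predicts multi-strand minimum-free-energy
    secondary structures with a reduced nearest-neighbor model, applies
    free-energy, conformation and seed-preservation filters, solves
    dilute-solution mass-action equilibria for the inherent complexes,
    classifies molecular-dynamics stability summaries, and simulates
    repression efficiency with an ODE model of cooperative target
    repression, reporting repression gains and synergy calls.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    deSolve,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
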