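Package: chofba
Title: Flux Balance Analysis and Cellular Energetics for CHO Fed-Batch Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational analysis of Chinese hamster ovary
    (CHO) fed-batch antibody production processes. Provides a reduced
    central-carbon stoichiometric network with SBML import/export,
    shape-constrained spline smoothing of fed-batch timecourses and
    derivation of cell-specific rates from dilution-corrected mass
    balances, ATP-maximizing flux balance analysis under measured-rate
    constraints, artificial-centering hit-and-run sampling of the
    constrained flux polytope for flux error estimation, and cellular
    energetics accounting (ATP production ledgers, ATP yield per c-mol of
    substrate, adenylate energy charge). A synthetic fed-batch generator
    with known ground truth emulates reference, CO2-stressed and
    base-free process phenotypes so that the whole pipeline can be
    exercised end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    pracma,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
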