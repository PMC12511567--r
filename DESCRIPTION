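Package: lipkin
Title: Membrane Lipid Composition and the Kinetics of E2 Ubiquitin Loading
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing how membrane lipid composition regulates a
    membrane-anchored E2 ubiquitin-conjugating enzyme. Implements a two-state
    conformational kinetic model of ubiquitin loading with a closed-form
    eigen-decomposition solution, a numerical ODE cross-check and global
    nonlinear least-squares fitting with a shared loading rate across
    conditions; a steady-state loading/discharge cycling model; Poisson
    mixture analysis of protein-membrane contact-count distributions with EM
    and BIC model selection; saturated-acyl-chain arithmetic for liposome
    compositions; C-Laurdan generalized polarization, FRET ratio and gel-lane
    quantification formulas; and seeded synthetic-data generators for every
    analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
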