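Package: kbsolv
Title: Kirkwood-Buff Analysis of Cosolvent Solutions and Cyclodextrin
    Force-Field Parameterization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for Kirkwood-Buff analysis of molecular-simulation and
    experimental data for cosolvent solutions, with an application to
    hydroxypropyl-beta-cyclodextrin (HPbCD). Computes radial distribution
    functions from particle trajectories with a finite-size correction for
    closed systems, integrates them to running Kirkwood-Buff integrals with
    block-averaged uncertainty, inverts binary-solution thermodynamic data
    (density, partial molar volumes, activity coefficients, compressibility)
    to Kirkwood-Buff integrals, decomposes preferential-interaction
    coefficients into side-chain and backbone contributions via the
    constant-increment method, evaluates geometric hydrogen-bond, cavity
    inclusion and rim-orientation metrics, and applies the ADD force-field
    hydroxyl parameter patch to CHARMM36-style cyclodextrin topologies.
    Includes synthetic-data generators with known ground truth so the whole
    pipeline is testable without molecular-dynamics runs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
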