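Package: vegferk
Title: Rule-Based Modeling of VEGFR2-SphK1-Calcium Signaling to ERK1/2
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A rule-based model of VEGF/VEGFR2 signal transduction to ERK1/2 in
    endothelial cells, in which sphingosine kinase 1 (SphK1), sphingosine
    1-phosphate (S1P) and intracellular calcium form the positive feedback loop
    that drives Ras/Raf/MEK/ERK activation. The package provides a minimal
    rule-based network expansion engine (molecule types, complex species with
    graph-canonical labels, reaction rules, closed mass-action networks, SBML
    export), a VEGFR1/VEGFR2/NRP1 receptor trafficking module, a PLCgamma/PKC/
    SphK1/S1P/Ras/Raf/MEK/ERK cascade, a two-pool IP3R/SERCA/PMCA/CRAC calcium
    module, a stiff ODE simulation layer with named observables, direct-search
    parameter fitting with Latin hypercube PRCC global sensitivity analysis,
    VEGF-dose and pVEGFR2-fraction threshold detection, anti-angiogenic therapy
    scans, and a synthetic-data generator for testing the inference stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    lhs,
    Rcpp,
    xml2,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
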