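Package: transglyco
Title: Thermodynamic Design of Nucleoside Phosphorylase Transglycosylation
    Reactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Equilibrium-state calculations for one-pot enzymatic
    transglycosylation of nucleoside analogues, in which a pyrimidine
    nucleoside phosphorylase and a purine nucleoside phosphorylase couple
    two reversible phosphorolysis reactions through shared phosphate and
    pentose-1-phosphate pools.  Solves the coupled mass-action equilibrium
    under conservation constraints, estimates phosphorolysis equilibrium
    constants of product nucleosides from observed equilibrium conversions,
    computes the sugar-donor excess required to reach a target product
    yield, quantifies conversions from HPLC-style peak-area data
    (calibration, retention-time peak assignment, dilution correction,
    plateau detection), and performs preparative mass-balance accounting.
    A synthetic-data generator produces reversible-kinetics time courses,
    noisy peak tables and process ledgers for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
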