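Package: chronotac
Title: Circadian Population Pharmacokinetic Models of Tacrolimus in
    Paediatric Renal Transplantation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two population pharmacokinetic models of oral tacrolimus with
    circadian modulation of clearance and absorption: a two-compartment
    model with a three-segment compartmental-absorption-and-transit (CAT3)
    gut, and a reduced whole-body physiologically based (PBPK) model with
    saturable red-blood-cell binding and hepatic intrinsic clearance.
    Includes FOCE population estimation with exponential inter-individual
    variability and covariate selection, boundary-constrained Bayesian and
    weighted-least-squares individual adaptation after formulation
    conversion, model evaluation tools (log-trapezoidal NCA,
    prediction-corrected visual predictive checks, Monte Carlo exposure
    simulation), and a virtual paediatric renal-transplant cohort
    generator so the full pipeline runs on synthetic data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
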