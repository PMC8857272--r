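Package: namdsim
Title: Drug-Disease Simulation of Visual Acuity Under Anti-VEGF Treatment in Neovascular AMD
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Indirect-response pharmacokinetic/pharmacodynamic modelling of
    best-corrected visual acuity (ETDRS letters) in patients with neovascular
    age-related macular degeneration treated with intravitreal ranibizumab.
    Simulates individual visual-acuity trajectories under arbitrary injection
    schedules, calibrates model parameters to cohort observations by nonlinear
    least squares, generates virtual patient cohorts matching published
    real-world summary statistics, and evaluates counterfactual treatment
    scenarios (treatment delay, undertreatment and loading, pandemic-related
    missed injections).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
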