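Package: petquant
Title: Brain PET Radioligand Quantification, Test-Retest Reliability, and
    Internal Dosimetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis pipeline for first-in-human brain PET
    radioligand studies. Builds metabolite-corrected arterial input
    functions from blood sample tables, fits one- and two-tissue
    compartment models and Logan graphical analysis to regional
    time-activity curves to estimate the total distribution volume (VT),
    performs model selection (AIC, F-test) and time-stability analysis,
    computes test-retest variability and one-way intraclass correlation
    over a cohort, and carries whole-body percent-injected-dose curves
    through retention fitting, MIRD residence times, S-value absorbed
    doses, and ICRP-60 effective dose. Includes a synthetic-data
    generator for input functions, brain kinetics cohorts, and
    whole-body biodistributions with controllable variance structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
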