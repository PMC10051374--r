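Package: pttdose
Title: Photothermal Therapy Dosimetry and Tumor Response Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis of nanoparticle-mediated photothermal therapy (PTT)
    experiments. Provides a lumped-capacitance model of laser heating and
    cooling with a temperature-threshold power controller, photothermal
    conversion efficiency (PCE) estimation from cooling curves by the
    energy-balance method, cumulative-equivalent-minutes (CEM) thermal dose
    with piecewise cell-death rate constants, caliper-based tumor volumetry
    with outcome classification and Kaplan-Meier survival summaries, and
    seeded generators of synthetic photothermal experiments and preclinical
    cohorts for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    survival,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
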