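Package: ebmr
Title: Event-Based Modelling of Biomarker Orderings and Patient Staging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Fits the sporadic-disease event-based model of disease progression
    to cross-sectional biomarker tables. Each biomarker is modelled as a
    two-component constrained normal mixture (normal versus abnormal), the
    maximum-likelihood ordering of biomarker abnormality events is found by
    multi-start greedy ascent over permutations, ordering uncertainty is
    characterised by Markov chain Monte Carlo positional variance diagrams and
    bootstrap resampling, and individual subjects are assigned a discrete model
    stage for classification and conversion prediction. Includes a synthetic
    cohort generator with known ground truth for validation, covering
    presymptomatic contamination of the control group and misdiagnosed
    patients.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
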