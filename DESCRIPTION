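Package: pressfilm
Title: Thickness-Artefact Error Analysis for Pressure-Sensitive Film Contact Measurements
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies the contact-width overestimation caused by the finite
    thickness of pressure-sensitive film (Fujifilm Prescale) in cylinder-on-flat
    indentation, as used in orthopaedic biomechanics. Provides the closed-form
    Hertzian line-contact width, empirical power-law models of film-measured
    width for metal-on-metal, metal-on-polymer and metal-on-bone pairings,
    the thickness-error ratio swept over diameter and force, a synthetic
    contact-patch renderer with station-averaged width measurement, a
    simulator of the full indentation experiment, and a total knee replacement
    condyle case study of contact-area error.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    png,
    jsonlite,
    yaml,
    withr,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'film-model.R'
    'materials.R'
    'hertz.R'
    'error-pipeline.R'
    'patch-imaging.R'
    'patch-io.R'
    'pressfilm-package.R'
    'synthetic-data.R'
    'record-io.R'
    'tkr-case-study.R'
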