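Package: osteoscreen
Title: Opportunistic Osteoporosis Screening from Radiograph Regions of Interest
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automated opportunistic osteoporosis screening from hip and
    lumbar-spine radiograph regions of interest: six-point vertebral morphometry
    with Genant-modified deformity criteria, automated radiograph quality
    assessment (implant/fracture exclusion, neighbour-deviation and
    minimum-vertebra rules), a pluggable bone-mineral-density regressor with a
    reference four-fold ensemble trainable on synthetic phantoms, T-score
    conversion and dual-threshold triage, and the agreement, calibration and
    discrimination statistics used to evaluate such screening tools. A synthetic
    phantom and cohort generator makes every stage testable without clinical
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
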