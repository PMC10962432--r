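Package: bdtrace
Title: Event-Aligned Biomarker Time-Courses in Brain-Dead Organ Donors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for reconstructing serum biomarker time-courses around
    confirmation of brain death from sparse, irregularly sampled donor serum
    panels. Implements a "post hoc cohort" workflow: simulation of donor
    panels with three clinically anchored sampling points, stratified
    balanced cohort construction over 5-hour blocks of brain-death duration,
    robust FDR-based outlier-donor exclusion (ROUT-style), and event-aligned
    asymmetric moving-median smoothing with qualitative trend
    classification, plus an end-to-end pipeline driver with run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
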