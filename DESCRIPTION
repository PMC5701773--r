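Package: RCVassess
Title: Preanalytical Interference Assessment with Reference Change Values
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for deciding whether a preanalytical intervention (for
    example, water intake shortly before phlebotomy) changes clinical
    chemistry analytes in a statistically and/or clinically meaningful way.
    Implements the reference change value (RCV) from analytical and
    within-subject biological variation, the desirable imprecision
    specification (DSI), per-subject and mean percent differences between
    paired basal and post-intervention measurements, an exact Wilcoxon
    signed-rank test for small paired samples, a three-tier significance
    classifier, table-style reports and interferogram plots, plus a
    variance-component simulator of paired analyte panels for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    S4Vectors,
    SummarizedExperiment,
    ggplot2,
    rlang,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'registry.R'
    'config.R'
    'change-metrics.R'
    'wilcoxon.R'
    'panel.R'
    'assess.R'
    'report.R'
    'interferogram.R'
    'simulate.R'
    'RCVassess-package.R'
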