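Package: COxPlateau
Title: Detection of Critical-Oxygenation Plateaus in Muscle NIRS Signals
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for defining and detecting muscle-oxygen-saturation
    (SmO2) plateaus ("critical oxygenation" plateaus) in wearable
    near-infrared spectroscopy (NIRS) time series recorded during
    3-min all-out cycling tests. Provides signal conditioning (5-s
    moving average, 1-Hz resampling), four threshold-based sliding
    window detection criteria (absolute and relative, 5 and 10 units),
    multi-rater consensus voting and Fleiss' kappa agreement analytics
    with Landis-Koch interpretation bands, cohort-level summaries and
    method-comparison matrices, and a seeded synthetic-trace generator
    producing ground-truth-labelled cohorts for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, yaml, jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'COxPlateau-package.R'
    'agreement_stats.R'
    'signal_io.R'
    'preprocessing.R'
    'plateau_detection.R'
    'synthetic_data.R'
    'cohort_summary.R'
    'cli.R'
    'methods-accessors.R'
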