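Package: tendomech
Title: Phase-Specific Tendon Biomechanics and Downstream Omics Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for phase-specific tendon mechanical testing
    (fascicle and interfascicular-matrix uniaxial tests): trace ingestion and
    protocol segmentation, preconditioning viscoelastic metrics (percentage
    hysteresis and stress relaxation), ramp-to-failure metrics (continuous
    tangent modulus or stiffness, yield at maximum modulus, failure
    properties, toe-region extension profiles), plus the downstream omics
    arithmetic used alongside such studies (label-free abundance
    normalisation and differential abundance, neopeptide turnover analysis
    with Benjamini-Hochberg FDR, efficiency-corrected relative qPCR
    expression, structure-function Pearson correlation) and the study-level
    statistical framework (normality gating, two-factor development x tendon
    ANOVA with Type-III sums of squares, compact letter displays, weighted
    kappa).  A quasi-linear-viscoelastic synthetic-data generator with
    analytic ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    car,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
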