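Package: fcreliab
Title: Test-Retest Reliability Analysis for Serial Functional Connectivity Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the reliability of edge-level functional
    connectivity in densely sampled (serial-scanning) designs. Implements
    counter-balanced session schedule generation and verification, synthetic
    multi-subject multi-condition multi-session data generation under a
    three-level Gaussian random-effects model with known variance components,
    ROI time-series processing (24-parameter motion expansion, polynomial and
    confound regression, pairwise Pearson connectivity, network-sorted edge
    vectorization), connectome fingerprinting with within- versus
    between-subject similarity summaries and identification accuracy,
    variance-component estimation by balanced-ANOVA method of moments and by
    restricted maximum likelihood for incomplete panels, between-condition and
    between-session intraclass correlation coefficients, network-level
    multivariate reliability (I2C2 trace estimator), scalar quality-measure
    reliability with one-way ANOVA condition tests, scan-duration
    pseudo-session analysis, and a reproducible end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr,
    yaml
Config/testthat/edition: 3
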