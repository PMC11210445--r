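Package: lipidlands
Title: Lipid Co-Regulation Network Analysis for Diagnosis-Genotype Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for targeted lipidomic panels profiled across clinical
    diagnosis by APOE-e4 carrier groups: quality filtering and mole-percent
    normalization, covariate residualization (ordinary least squares, or a
    donor random-intercept mixed model for repeated serum draws), differential
    screening against a reference group, weighted lipid correlation network
    analysis (WLCNA) with topological overlap, module eigenlipids and
    group-level statistics, sample clustering with per-cell Fisher enrichment,
    per-feature cognition-slope association models with false discovery rate
    control, and bootstrap mediation analysis of education. A synthetic cohort
    generator with planted co-regulated modules makes the full pipeline
    testable without restricted-access data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    cluster,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
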