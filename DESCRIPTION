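Package: sleepcca
Title: Canonical Correlation Pipeline Linking Multidimensional Sleep to
    Biopsychosocial and Connectome Measures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for two-block canonical correlation analysis
    (CCA) linking a small block of sleep-quality sub-scores to a wide block
    of behavioral, health and demographic measures, with inference that
    respects family structure in twin/sibling cohorts: restricted
    permutations over exchangeability blocks, bootstrap stability of
    structure coefficients, and family-aware k-fold cross-validation.
    Downstream, per-subject functional-connectivity matrices are assembled
    from parcel time series with motion censoring, residualized for
    confounds, and related to CCA composite scores via edge-wise and
    network-wise linear models; the resulting coefficient networks are
    characterized with module-degree z-scores, participation coefficients
    and an integration/segregation ratio. A synthetic-cohort generator with
    planted canonical correlations, family-induced intra-class correlation
    and planted connectivity effects makes every stage testable without
    restricted-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
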