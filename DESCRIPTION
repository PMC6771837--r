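Package: mvbmeta
Title: Univariate and Multivariate Random-Effects Meta-Analysis of
    Correlated Binary Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for jointly meta-analysing multiple correlated binary
    outcomes reported as 2x2 tables. Derives log odds ratios with
    continuity-correction and zero-event rules, computes analytic
    within-study correlations for structurally related outcomes
    (mutually exclusive or subset pairs), and fits random-effects
    models by restricted maximum likelihood: standard univariate
    meta-analysis, the fully hierarchical multivariate model with
    within-study covariance matrices, and the Riley overall-correlation
    model that amalgamates within- and between-study correlation.
    Includes side-by-side univariate-versus-multivariate comparison
    tables, forest and contour-enhanced funnel diagnostics for
    small-study effects, and a synthetic-data generator for correlated
    binary meta-analysis datasets with heterogeneity, structural
    outcome relations and missing-outcome mechanisms (including
    significance-driven selective reporting).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    pracma,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    metafor,
    Matrix,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
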