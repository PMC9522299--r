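Package: idprel
Title: Multi-Site Reliability Analysis for Imaging-Derived Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for assessing scanner-site effects and test-retest
    reliability of imaging-derived phenotypes (IDPs) in travelling-heads
    designs. Implements per-phenotype repeated-measures ANOVA with
    Shapiro-Wilk normality and Mauchly sphericity diagnostics and
    Greenhouse-Geisser correction, Friedman rank cross-checks, class-wise
    false-discovery-rate control, consistency intra-class correlation
    ICC(3,1) from variance components (closed-form ANOVA and REML),
    pairwise-site ICCs and correlation matrices, benchmarking against a
    large test-retest reference cohort by subsample resampling with
    empirical two-sided p-values, analytic power for the within-subject
    site-effect test via the noncentral F distribution, and synthetic
    cohort generators with known variance components for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
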