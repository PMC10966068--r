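Package: asymkit
Title: Multivariate Structural Brain Asymmetry Patterns in Copy Number
    Variant Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how rare copy number variants (CNVs) shift
    structural brain asymmetry. Computes left-right asymmetry indices from
    paired regional gray-matter volumes, learns per-CNV case-control patterns
    with regularized linear discriminant analysis, assesses coefficient
    robustness with a sign-aligned bootstrap procedure, compares asymmetry
    signatures across CNVs with spin-permutation map-similarity tests and
    Ward clustering, quantifies hemispheric effect sizes with bootstrap
    confidence intervals, and functionally annotates coefficient maps against
    term-activation tables by correlation and binned weighted-score decoding.
    Includes a synthetic-cohort generator with planted per-region asymmetry
    shifts so the full pipeline is testable without clinical data access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
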