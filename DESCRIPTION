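Package: mutcva
Title: Mutation-Profile Canonical Variates Analysis for Malignancy Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds binary variant-by-sample and gene-count mutation matrices
    from targeted hotspot-panel variant calls, applies depth/strand/population
    frequency retention rules and matched tumor/normal pair subtraction, fits a
    two-group canonical variates (Fisher discriminant) analysis with univariate
    F-ratio screening and structure correlations, derives an F-sum malignancy
    risk score with a zero-mutation classification cutoff, and reports
    resubstitution diagnostic metrics. Includes a synthetic cohort generator
    reproducing the statistical structure of a papillary thyroid carcinoma
    tumor/tumor-free study so the full pipeline is testable without external
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    MASS,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
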