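Package: mrforge
Title: Bidirectional and Multivariable Two-Sample Mendelian Randomization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A complete two-sample Mendelian randomization toolkit for GWAS
    summary statistics: instrument selection (genome-wide significance, LD
    clumping, proxy substitution, MAF and palindrome filters, F statistics),
    allele harmonization, causal estimation (Wald ratio, fixed- and
    multiplicative-random-effects inverse-variance weighting, MR-Egger,
    weighted median, multivariable IVW), and sensitivity machinery
    (Cochran's Q, leave-one-out, MR-PRESSO global/outlier/distortion tests,
    Steiger directionality, non-centrality-based power, and
    Benjamini-Hochberg FDR). Includes a synthetic summary-statistics
    generator with a known causal model so every estimator and diagnostic
    is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
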