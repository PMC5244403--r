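Package: mrsum
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for bidirectional two-sample Mendelian randomization from
    GWAS summary statistics: reading and harmonizing per-SNP association
    records onto a common effect allele, LD-aware instrument selection
    (stepwise pruning and proxy lookup against a user-supplied correlation
    matrix), causal-effect estimation by Wald ratio, fixed- and random-effects
    inverse-variance weighting, generalized least squares and profile
    maximum likelihood for correlated instruments, and MR-Egger regression
    with its pleiotropy intercept test. Includes Cochran's Q and I-squared
    heterogeneity statistics with test-based confidence intervals,
    conversion of estimates to the per-doubling-of-odds scale, a power
    approximation for binary outcomes, a synthetic summary-statistics
    generator with known ground truth, and a config-driven analysis
    pipeline producing per-SNP forest tables and machine-readable reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    utils,
    withr,
    yaml
Suggests:
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
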