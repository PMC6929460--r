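Package: wscan
Title: Data-Adaptive W-Test Scans for SNP-SNP and SNP-CpG Epistasis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Case-control association and epistasis testing with the W-test, a
    scaled sum of squared standardized per-category log odds ratios referred to
    a chi-squared distribution whose scale (h) and degrees of freedom (f) are
    either category-count defaults or estimated from permutation-null bootstrap
    samples by moment matching. Supports main-effect scans, pairwise and
    higher-order SNP interaction scans with candidate screening and Bonferroni
    thresholds, cis SNP-CpG (gene-methylation) interaction scans with
    two-means binarization of methylation beta values, post-test distributional
    diagnostics (per-k goodness of fit, p-value QQ data), seeded synthetic
    cohort generation, and delimited-text readers and writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    graphics,
    grDevices,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
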