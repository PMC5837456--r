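Package: phenomescan
Title: Automated Phenome Scans for Biobank-Style Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based engine for phenome-wide association scans (pheWAS,
    MR-pheWAS, EnWAS) over heterogeneous biobank phenotype tables. Each field is
    automatically coded as continuous, ordered categorical, unordered
    categorical or binary via a decision flow (first-occurrence selection,
    array averaging, negative-value recoding, inverse rank-normal
    transformation, equal-mass binning, integer distinct-value rules,
    data-coding driven ordering, binary expansion of multi-valued fields), then
    tested against a trait of interest with the matching regression (linear,
    ordinal logistic, multinomial logistic or binomial) adjusted for
    confounders. Results are ranked, Bonferroni-corrected, and exported as
    tables, QQ and forest plots, and a hierarchical JSON for interactive
    visualization. Includes a synthetic-cohort simulator with known ground
    truth for validation, and a partitionable command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    MASS,
    nnet,
    jsonlite,
    ggplot2,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
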