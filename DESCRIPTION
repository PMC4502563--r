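Package: clutraffic
Title: Quantification of Clusterin Trafficking and Secretion Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested, seeded pipeline for quantifying endoplasmic-reticulum
    retention of clusterin (CLU) reporter constructs. Simulates multi-channel
    fluorescence fields of cells with genotype-dependent trafficking
    phenotypes and ELISA/western secretion assays with known ground truth;
    measures per-cell Golgi-enrichment ratios and ER colocalization (Pearson)
    with automatic-threshold Golgi segmentation and low-signal exclusion;
    converts conditioned-medium versus lysate assays into secreted fractions
    with matrix-background subtraction and TGF-beta1 normalization; and
    provides the group-statistics layer (3-SD outlier removal, ANOVA with
    Tukey HSD contrasts against wild type, Bonferroni thresholding across
    constructs, and the Cochran-Mantel-Haenszel test with Mantel-Haenszel
    common odds ratio and Robins-Breslow-Greenland confidence interval over
    experiment strata).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    rlang,
    withr,
    tibble,
    dplyr,
    tidyr,
    jsonlite,
    yaml,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
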