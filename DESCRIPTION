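Package: skinclock
Title: Second-Generation Epigenetic Clocks for Skin Aging Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Trains and validates DNA-methylation clocks for panel-rated
    skin aging phenotypes (wrinkle grade, visual facial age, and visual
    age progression), starting from beta-value matrices. Provides probe
    filtering and quantile normalization, identification of low-methylated
    regions (LMRs) from whole-genome bisulfite sequencing counts with
    FDR-calibrated cutoff selection, region-level feature aggregation,
    ridge regression with cross-validated lambda-path selection, validation
    statistics (MAE, Pearson tests, exact Wilcoxon rank-sum), preranked
    gene-set enrichment with a weighted Kolmogorov-Smirnov statistic, and a
    multi-source pathway consensus. A synthetic-cohort generator emulating
    multi-rater phenotype noise and planted methylation signal makes every
    stage testable without access to restricted cohort data.
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
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    glmnet
Config/testthat/edition: 3
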