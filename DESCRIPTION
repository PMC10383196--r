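Package: svrgwas
Title: SVR-Mediated and FarmCPU Genome-Wide Association for Plant
    Breeding Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A genome-wide association pipeline for plot-level plant
    breeding trials, implementing two complementary scans: FarmCPU
    (iterative circulation between a fixed-effect per-SNP model with
    pseudo-QTN covariates and a random-effect model that selects those
    pseudo-QTNs, thresholded by Benjamini-Hochberg FDR) and SVR-mediated
    GWAS (cross-validated support vector regression variable importance
    per SNP, scaled 0-100, with a global empirical permutation
    threshold).  Includes nearest-neighbour spatial adjustment of field
    plots, outlier screening, mixed-model BLUPs and heritability,
    genotype quality control with Markov-chain imputation, VanRaden
    kinship and principal-component structure covariates, LD decay
    estimation, peak-anchored QTL region extraction with annotation
    co-localization, and a synthetic-data generator that plants known
    QTL so power and calibration are verifiable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    kernlab,
    lme4,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    vcfR,
    withr
Suggests:
    e1071,
    purrr,
    rtracklayer,
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
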