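Package: mrsomics
Title: Merging Tissue HR MAS MR Spectroscopy and Gene Expression Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for joint analysis of high-resolution magic angle spinning
    (HR MAS) proton MR spectra and two-color gene-expression microarrays
    measured on the same tumor tissue samples. Provides two-color array
    preprocessing (background subtraction, within-array loess and
    green-channel quantile normalization, local least squares imputation,
    probe filtering and collapsing), Voigt-lineshape peak fitting with
    TSP-referenced absolute metabolite quantification, nearest-centroid
    intrinsic molecular subtyping, unsupervised metabolic subgrouping of
    spectra (Spearman dissimilarity, complete-linkage clustering,
    multidimensional scaling, point-wise spectral t-tests), empirical-Bayes
    moderated differential expression with maxmean permutation gene-set
    analysis, and minimal-hypergeometric (mHG) enrichment of
    metabolite-correlated ranked gene lists. A seeded synthetic-data
    generator produces paired spectra, raw arrays, gene sets and centroids
    with planted structure so every stage can be validated without access
    to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
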