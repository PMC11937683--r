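Package: methelas
Title: Methylome Aging Contrasts, DMR Calling, and Tissue Elasticity Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for whole-genome bisulfite methylome studies of
    skeletal muscle aging and Dnmt3a overexpression, and for fasting-refeeding
    metabolic elasticity experiments. Provides readers and writers for
    Bismark-style coverage tables and BED annotations, a beta-binomial
    methylome simulator with planted age- and genotype-associated
    differentially methylated regions (DMRs), coverage filtering and
    window/feature aggregation, PCA and hierarchical clustering of methylation
    matrices, a segmentation-based DMR caller with Kolmogorov-Smirnov and
    Mann-Whitney region tests and nearest-gene annotation, age-DMR
    classification with a Dnmt3a-sensitivity contrast, HpaII/MspI
    (MIAMI-style) two-enzyme methylation classification of array probes, and
    the spreadsheet-defined Tissue Elasticity Score (ElaS) with
    fed/fasted/refed gene-responsiveness summaries. A config-driven pipeline
    orchestrates end-to-end simulated runs with reproducibility manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
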