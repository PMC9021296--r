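Package: degrescue
Title: Treatment-Rescue Differential Expression Analysis for Bulk and
    Single-Cell Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying how far a pharmacological treatment
    restores a disease transcriptome toward its control state. Implements
    negative-binomial likelihood-ratio differential expression with
    iterative DEG-elimination (DEGES-style) normalization for four-group
    bulk designs, Venn-based classification of differentially expressed
    genes into Restored, Maintained and New rescue classes with a
    restoration-magnitude summary, keyword-based curation of lipid, immune
    and synapse gene categories with hypergeometric over-representation,
    immediate-early-gene panel z-score analysis with factorial ANOVA and
    Dunnett contrasts, and single-cell immune-cell landscape statistics
    (QC filtering, subcluster composition, lineage activation scores and
    Wilcoxon rank-sum marker detection). Ships seeded synthetic-data
    generators that emulate the four-group study design with ground-truth
    labels for every downstream stage.
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
    Matrix,
    methods,
    multcomp,
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
    DESeq2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
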