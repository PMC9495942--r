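Package: mirbias
Title: Expression-Bias Screening of miRNA Target Sets and Circulating
    Biomarker Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico screen that ranks microRNAs by the expression bias
    of their target genes in lesion-versus-eutopic transcriptomes, built
    around a per-miRNA chi-square contingency test against the genome
    background with Bonferroni correction, together with the downstream
    analyses such a screen feeds: relative qPCR quantification by the
    2^-delta-delta-Ct model, ROC evaluation of single- and combined-marker
    plasma panels (AUC with DeLong confidence intervals, Youden cutoffs,
    predictive values and likelihood ratios), factorial ANOVA with
    Student-Newman-Keuls and Monte-Carlo Dunnett post-hoc tests, Spearman
    symptom correlations and cohort-table statistics. A synthetic-data
    module generates target atlases, transcriptomes, Ct matrices and
    transfection designs with planted effects so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    knitr,
    multcomp,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
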