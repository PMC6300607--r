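Package: spliceswitch
Title: Differential Splice-Junction Usage, Splicing-Event Classification
    and Drug-Synergy Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained pipeline for junction-level splicing analysis
    of two-condition RNA-seq experiments: parsing of GTF gene models and
    STAR splice-junction counts, a beta-binomial likelihood-ratio test for
    differential relative junction usage with Benjamini-Hochberg FDR
    control, rule-based classification of significant junctions into
    alternative-splicing event types (exon skipping/inclusion, intron
    retention, alternative 5'/3' splice sites, alternative transcript
    ends), gene-level aggregation, a long/short isoform-switch score,
    hypergeometric and Fisher exact overlap statistics, and
    Bliss-independence synergy scoring of two-drug dose matrices. Includes
    a synthetic-data generator that emits annotations, junction-count
    matrices with programmed splicing events of known truth, and dose
    matrices with programmed interaction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    fgsea,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
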