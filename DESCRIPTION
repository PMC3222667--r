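Package: snpanel
Title: Transcriptome SNP Discovery, Genotyping Panel Design and Validation
    Statistics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for single nucleotide polymorphism (SNP) marker
    development from de novo assembled transcriptomes of non-model species.
    Calls candidate SNPs from per-contig read pileups under explicit read-count
    rules, computes the descriptor variables used to judge genotyping-assay
    suitability (flanking-region availability, flank mismatch count Q, a
    documented surrogate of the Illumina Assay Design Tool score, comparative
    intron-exon boundary prediction, synonymous/non-synonymous effect coding),
    selects ranked assay panels, and analyses genotyping validation outcomes
    with the statistical battery of platform-comparison studies
    (Yates-corrected chi-square, Monte-Carlo Mann-Whitney, paired Wilcoxon,
    binomial logistic regression with backward Wald elimination, ROC analysis
    with DeLong variance). A seeded simulator generates barcode-tagged reads
    under long-read and short-read platform profiles together with truth
    tables, so every stage is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
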