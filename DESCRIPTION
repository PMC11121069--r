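Package: devage
Title: Developmental-Time Splice Variant, Epigenetic Clock, and SNP-Methylation
    Association Analysis for Mouse Fetal Brain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable, tested reimplementation of an integrative analysis of
    fetal brain development in mouse strains differing in longevity.  Provides
    developmental-time-specific splice-variant classification from multi-sample
    STAR-style junction tables (merge, overhang/read-support filters, S/NS and
    known/novel calls, motif and per-gene summaries), epigenetic-clock DNA
    methylation comparison (beta-to-M transform, per-site ANOVA differential
    methylation calls, Venn partitions, hierarchical clustering with cophenetic
    dendrogram comparison), SNP-methylation proximity enrichment (nearest
    distances, distance bins, 2x2 contingency tables with one-sided Fisher
    exact tests and conditional-MLE odds ratios), and contingency statistics on
    differential-expression count tables (Pearson chi-square with Cramer's V,
    strain-specific Venn partitions, between-timepoint expression correlation).
    A synthetic-data generator with recorded planted truth emulates the study
    design so every stage is testable without the deposited raw data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    yaml,
    withr,
    vcfR,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
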