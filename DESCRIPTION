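Package: medipdiff
Title: Paired Differential Methylation and Expression Analysis for
    MeDIP-Seq and mRNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A paired case/control analysis pipeline for MeDIP-seq
    methylation enrichment data and mRNA-seq gene expression data.
    Candidate differentially methylated regions (DMRs) are built by
    merging the peak calls of each sample pair; true DMRs are called by a
    2x2 chi-square test on region read counts against library sizes with
    false discovery rate control and a fold-change filter, then
    classified into uptrend and downtrend regions. Genes are classified
    per element (promoter, 5'-UTR, CDS, intron, 3'-UTR) as hyper- or
    hypo-methylated from the trend of overlapping DMRs. Differential
    expression is called per pair from RPKM values with the
    Audic-Claverie exact count test, Benjamini-Yekutieli FDR control and
    a fold filter, then aggregated across pairs. Hypergeometric term
    enrichment with Bonferroni correction, methylation-expression
    integration, MeDIP-seq read and peak QC statistics, and a fully
    deterministic truth-labelled synthetic data generator complete the
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    data.table,
    stats,
    tools,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
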