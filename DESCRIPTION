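Package: oncohist
Title: Integrative Mapping of Oncohistone Occupancy and Transcriptional Output
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative pipeline for studying how a mutant (onco-) histone
    reshapes transcription. Calls differential gene expression (RNA-seq) and
    differential RNA polymerase II occupancy (PRO-seq) from count matrices with
    a negative-binomial Wald test; calls mutant-histone-specific CUT&RUN peaks
    from FLAG-tagged histone coverage normalized against an H2A internal-control
    track; tests the genomic distribution of those peaks against a
    length-preserving shuffled null with a chi-square test; quantifies
    co-localization with ATAC-seq open-chromatin peaks; scores locus-wide
    mutant-histone enrichment per gene over the window from 1 kb upstream of the
    TSS to the TES; and tests gene sets for occupancy enrichment with a GSEA
    running-sum statistic under a set-membership permutation null. A
    synthetic-data module generates genomes, annotations, negative-binomial
    count matrices and binned coverage tracks with planted ground truth so the
    whole pipeline is exercisable and testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    DESeq2,
    withr
Config/testthat/edition: 3
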