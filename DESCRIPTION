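Package: cnvreg
Title: Consensus CNV Filtering, CNVR Construction, and Pedigree-Based
    Validation for Whole-Genome Sequence Call Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for population-scale copy number variation (CNV) surveys
    from whole-genome sequence call sets. Implements two-caller consensus
    filtering of per-sample CNV calls by one-way overlap fraction, merging
    of calls within and across samples into copy number variable regions
    (CNVRs) under a pairwise reciprocal-overlap criterion, gain/loss/mixed
    typing, parent-offspring trio transmission and inheritance rates with a
    derived call error rate, overlap of CNVRs with gene and QTL annotation
    tracks, Fisher's exact trait enrichment and binomial term
    overrepresentation with Benjamini-Hochberg correction, per-chromosome
    distribution summaries, and a pedigree-aware synthetic call-set
    generator with known truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    igraph,
    IRanges,
    withr
Config/testthat/edition: 3
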