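#!/usr/bin/env Rscript
## Annotation of the CNVR set: gene overlap (1 bp rule), breed-specific
## regions, and Fisher's exact QTL trait enrichment with BH correction.

suppressPackageStartupMessages(library(cnvreg))

genome <- read_genome("results/sim/genome.tsv")
ped <- read_pedigree("results/sim/pedigree.tsv")
cnvrs <- read_cnvr_bed("results/cnvrs.bed")
genes <- read_features("results/sim/genes.bed")
qtl <- read_features("results/sim/qtl.bed")

ov <- overlap_features(cnvrs, genes, genome = genome)
utils::write.table(ov, "results/cnvr_gene_overlap.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
roll <- overlap_rollup(ov)
cat(sprintf("gene overlap: %d CNVRs overlap %d features (%d pairs)\n",
            roll$n_cnvrs_overlapped, roll$n_features_overlapped,
            roll$n_pairs))
print(roll$features_per_class)

bs <- breed_specific(cnvrs, ped)
utils::write.table(
  bs[, c("chrom", "start", "end", "cnvr_id", "type", "frequency", "breed",
         "single_carrier")],
  "results/breed_specific.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("breed-specific CNVRs: %d (%.0f%% single-carrier)\n",
            nrow(bs), 100 * attr(bs, "prop_single_carrier")))

enr <- qtl_enrichment(cnvrs, qtl, alpha = 0.05)
utils::write.table(enr, "results/qtl_enrichment.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("QTL enrichment: %d traits tested, %d significant (BH < 0.05)\n",
            nrow(enr), sum(enr$significant)))
print(utils::head(enr, 5))
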