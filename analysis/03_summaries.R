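#!/usr/bin/env Rscript
## Descriptive statistics of the CNVR set: per-chromosome distribution,
## genome coverage, size and carrier-frequency spectra.

suppressPackageStartupMessages(library(cnvreg))

genome <- read_genome("results/sim/genome.tsv")
cnvrs <- read_cnvr_bed("results/cnvrs.bed")

cs <- chromosome_summary(cnvrs, genome)
utils::write.table(cs$table, "results/chromosome_summary.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
gc <- genome_coverage(cnvrs, genome)
st <- size_frequency_stats(cnvrs)

cat("Per-chromosome distribution written to results/chromosome_summary.tsv\n")
print(cs$table)
cat(sprintf("mean per-chromosome coverage: %.2f%%\n", cs$mean_ratio_pct))
cat(sprintf("genome coverage: %d unique bp (%.2f%%)\n",
            gc$unique_bp, 100 * gc$fraction))
cat(sprintf("r(chromosome length, CNVR count) = %.2f\n", cs$r_length_count))
cat(sprintf("CNVR length: %.0f-%.0f bp, mean %.0f, median %.0f\n",
            st$min_len, st$max_len, st$mean_len, st$median_len))
cat(sprintf("carrier counts: 1-%d\n", max(which(st$freq_spectrum > 0))))
jsonlite::write_json(
  list(genome_coverage = gc, mean_chromosome_ratio = cs$mean_ratio,
       r_length_count = cs$r_length_count,
       size = st[c("n", "min_len", "max_len", "mean_len", "median_len")],
       type_counts = as.list(st$type_counts)),
  "results/summary.json", auto_unbox = TRUE, digits = NA)
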