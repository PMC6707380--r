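#!/usr/bin/env Rscript
## Generate the synthetic study data set: a pedigree-structured population
## (three founder breeds + 12 trios) observed by two imperfect CNV callers,
## with gene and QTL tracks. All downstream drivers read from results/sim/.

suppressPackageStartupMessages(library(cnvreg))

seed <- 17
sim <- simulate_cnv_data(sim_config(), seed = seed)
write_simulation(sim, "results/sim")

cat("Simulated data set (seed", seed, ")\n")
print(sim)
cat(sprintf("  carried sample-locus pairs: %d\n", sum(sim$genotypes >= 1)))
cat(sprintf("  mean coverage: %.1fx (range %.1f-%.1f)\n",
            mean(sim$pedigree$coverage), min(sim$pedigree$coverage),
            max(sim$pedigree$coverage)))
cat("files written under results/sim/\n")
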