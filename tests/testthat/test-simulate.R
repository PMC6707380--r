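test_that("simulation is deterministic given the seed", {
  cfg <- sim_config(n_loci = 50)
  a <- simulate_cnv_data(cfg, seed = 21)
  b <- simulate_cnv_data(cfg, seed = 21)
  expect_identical(a$calls_primary, b$calls_primary)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$pedigree, b$pedigree)
  c <- simulate_cnv_data(cfg, seed = 22)
  expect_false(identical(a$calls_primary, c$calls_primary))
})

test_that("noiseless calls coincide exactly with carried truth loci", {
  sim <- simulate_cnv_data(noiseless(sim_config(n_loci = 80)), seed = 2)
  key <- paste(sim$loci$chrom, sim$loci$start, sim$loci$end)
  for (calls in list(sim$calls_primary, sim$calls_support)) {
    expect_true(all(paste(calls$chrom, calls$start, calls$end) %in% key))
    # one call per carried locus per sample
    expect_equal(nrow(calls), sum(sim$genotypes >= 1))
  }
})

test_that("genotypes are Mendelian and respect sex-chromosome ploidy", {
  sim <- simulate_cnv_data(sim_config(n_loci = 150), seed = 8)
  geno <- sim$genotypes; ped <- sim$pedigree
  slots <- sapply(ped$sample, function(smp)
    expected_ploidy(sim$loci$category, ped$sex[ped$sample == smp]))
  expect_true(all(geno <= slots))          # never more alleles than slots
  expect_true(all(geno >= 0))
  kids <- ped[!is.na(ped$sire), ]
  for (k in kids$sample) {
    sire_g <- geno[, kids$sire[kids$sample == k]]
    dam_g <- geno[, kids$dam[kids$sample == k]]
    kid_g <- geno[, k]
    # a child allele must trace to a parent allele: no carrier child at a
    # locus where both parents are non-carriers
    expect_true(all(kid_g[sire_g + dam_g == 0] == 0))
    # at most one autosomal allele can come from each parent
    auto <- sim$loci$category == "autosome"
    expect_true(all(kid_g[auto] <= (sire_g[auto] >= 1) + (dam_g[auto] >= 1)))
    # sons carry no paternal X
    sex <- ped$sex[ped$sample == k]
    x <- sim$loci$category == "X"
    if (sex == "male") expect_true(all(kid_g[x] <= pmin(dam_g[x], 1)))
  }
})

test_that("false-negative rate thins child calls binomially", {
  cfg <- noiseless(sim_config(n_loci = 400))
  cfg$fn_base <- 0.2   # flat 20% FN (fn_range stays 0)
  sim <- simulate_cnv_data(cfg, seed = 14)
  n_carried <- sum(sim$genotypes >= 1)
  n_emitted <- nrow(sim$calls_primary)
  expect_lt(abs(n_emitted - 0.8 * n_carried),
            4 * sqrt(n_carried * 0.2 * 0.8))
})

test_that("caller-A-only false positives are removed by the consensus filter", {
  cfg <- noiseless(sim_config(n_loci = 60))
  sim <- simulate_cnv_data(cfg, seed = 4)
  base <- filter_supported_calls(sim$calls_primary, sim$calls_support,
                                 samples = sim$pedigree$sample)
  # add 50 independent A-only false positives far from the loci pattern
  set.seed(99)
  s <- sample.int(4e6, 50) + 5e6
  fp <- mk_calls(s, s + 500, chrom = "chr1",
                 sample = sample(sim$pedigree$sample, 50, replace = TRUE),
                 caller = "callerA")
  with_fp <- filter_supported_calls(rbind(sim$calls_primary[names(fp)], fp),
                                    sim$calls_support,
                                    samples = sim$pedigree$sample)
  expect_equal(with_fp[c("chrom", "start", "end", "sample")],
               base[c("chrom", "start", "end", "sample")],
               ignore_attr = "row.names")
})

test_that("an infeasible locus plan errors rather than looping forever", {
  small <- data.frame(chrom = "chr1", length = 5e4, category = "autosome")
  cfg <- sim_config(chromosomes = small, n_loci = 400)
  expect_error(simulate_cnv_data(cfg, seed = 1), "could not place")
})

test_that("written simulations can be read back by the pipeline readers", {
  dir <- withr::local_tempdir()
  sim <- simulate_cnv_data(sim_config(n_loci = 40), seed = 6)
  write_simulation(sim, dir)
  genome <- read_genome(file.path(dir, "genome.tsv"))
  expect_equal(genome$chrom, sim$genome$chrom)
  calls <- read_calls(file.path(dir, "calls_callerA.tsv"), genome)
  expect_equal(nrow(calls), nrow(sim$calls_primary))
  ped <- read_pedigree(file.path(dir, "pedigree.tsv"))
  expect_equal(nrow(ped), nrow(sim$pedigree))
  expect_equal(nrow(derive_trios(ped)), 12)
  genes <- read_features(file.path(dir, "genes.bed"))
  expect_equal(nrow(genes), nrow(sim$genes))
})
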