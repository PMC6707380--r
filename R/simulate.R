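## Pedigree-structured synthetic CNV call sets with known truth.
##
## The generator emulates the design of a population-scale two-caller CNV
## survey: three founder breeds, parent-offspring trios, diploid autosomes
## with sex-dependent X ploidy, rare skewed-frequency CNV loci with
## log-normal lengths, and two imperfect callers with boundary jitter,
## coverage-dependent false negatives, and random false positives.

#' Configuration for the synthetic CNV survey generator
#'
#' Defaults describe a desk-scale version of a 240-animal swine survey:
#' three founder breeds, 12 trios, a 20 Mb three-chromosome genome (two
#' autosomes and an X), 300 CNV loci with log-normal lengths (median
#' 2.9 kb, mean 6.8 kb), mostly losses, low skewed carrier frequencies,
#' per-sample coverage with mean near 13.6x, and caller noise knobs.
#'
#' @param chromosomes Data.frame `chrom`, `length`, `category`.
#' @param founders Named integer vector: founder count per breed (split
#'   evenly male/female).
#' @param n_trios Number of parent-offspring trios to plan.
#' @param n_loci Number of true CNV loci.
#' @param len_meanlog,len_sdlog Log-normal locus length parameters (bp).
#' @param min_locus_len,max_locus_len Clamp on locus lengths (bp).
#' @param gain_frac Fraction of loci that are copy-number gains.
#' @param af_shape1,af_shape2 Beta parameters for per-breed allele
#'   frequencies of each locus.
#' @param cov_shape,cov_rate Gamma parameters for per-sample mean coverage
#'   (x), clamped to `[1, 31]`.
#' @param jitter_sd Caller boundary jitter standard deviation (bp).
#' @param fn_base,fn_range,fn_cov_mid,fn_cov_scale False-negative
#'   probability as a logistic function of coverage:
#'   `fn_base + fn_range * plogis((fn_cov_mid - coverage) / fn_cov_scale)`
#'   (roughly doubles below 5x relative to 20x at the defaults).
#' @param fp_per_mb Expected false-positive calls per Mb per caller per
#'   sample.
#' @param child_fp_prop Proportion of each trio child's carried regions
#'   that are planted caller-concordant false positives (0 disables; used
#'   for validation experiments).
#' @param n_genes,gene_planted_frac,n_qtl,n_traits Annotation-track
#'   generation: gene count, fraction of genes planted inside CNV loci,
#'   QTL record count, number of distinct trait labels.
#' @return A `cnv_sim_config` list.
#' @export
sim_config <- function(
    chromosomes = data.frame(
      chrom = c("chr1", "chr2", "chrX"),
      length = c(10e6, 5e6, 5e6),
      category = c("autosome", "autosome", "X"),
      stringsAsFactors = FALSE),
    founders = c(Duroc = 16L, Landrace = 16L, Yorkshire = 16L),
    n_trios = 12L,
    n_loci = 300L,
    len_meanlog = log(2900), len_sdlog = 1.3,
    min_locus_len = 250L, max_locus_len = 400000L,
    gain_frac = 0.05,
    af_shape1 = 0.6, af_shape2 = 3,
    cov_shape = 3.2, cov_rate = 0.235,
    jitter_sd = 100,
    fn_base = 0.05, fn_range = 0.10, fn_cov_mid = 8, fn_cov_scale = 3,
    fp_per_mb = 0.5,
    child_fp_prop = 0,
    n_genes = 200L, gene_planted_frac = 0.3,
    n_qtl = 150L, n_traits = 15L) {
  cfg <- as.list(environment())
  cfg$chromosomes <- validate_genome(chromosomes)
  stopifnot(all(founders > 0), n_trios >= 1, n_loci >= 1,
            gain_frac >= 0, gain_frac <= 1, jitter_sd >= 0,
            fn_base >= 0, fn_base + fn_range <= 1, fp_per_mb >= 0,
            child_fp_prop >= 0, child_fp_prop < 1)
  structure(cfg, class = "cnv_sim_config")
}

#' Noise-free variant of a simulation configuration
#'
#' Zeroes boundary jitter and both error rates, so every emitted call
#' matches a truth locus exactly in both callers.
#'
#' @param config A [sim_config()] object.
#' @return The modified configuration.
#' @export
noiseless <- function(config = sim_config()) {
  config$jitter_sd <- 0
  config$fn_base <- 0; config$fn_range <- 0
  config$fp_per_mb <- 0
  config$child_fp_prop <- 0
  config
}

fn_prob <- function(cov, cfg) {
  cfg$fn_base + cfg$fn_range *
    stats::plogis((cfg$fn_cov_mid - cov) / cfg$fn_cov_scale)
}

# Sample n non-overlapping intervals on the genome with given lengths.
# `avoid` (optional interval df) is also kept clear. Errors if the plan
# cannot be placed.
place_intervals <- function(n, lens, genome, avoid = NULL, max_tries = 500L) {
  occ_s <- occ_e <- stats::setNames(
    rep(list(numeric(0)), nrow(genome)), genome$chrom)
  if (!is.null(avoid)) {
    for (ch in unique(avoid$chrom)) {
      occ_s[[ch]] <- avoid$start[avoid$chrom == ch]
      occ_e[[ch]] <- avoid$end[avoid$chrom == ch]
    }
  }
  chrom <- character(n); start <- numeric(n); used_len <- numeric(n)
  w <- genome$length / sum(genome$length)
  lens <- sort(lens, decreasing = TRUE)   # place large loci first
  for (i in seq_len(n)) {
    done <- FALSE
    for (try in seq_len(max_tries)) {
      ch <- sample(genome$chrom, 1, prob = w)
      L <- genome$length[genome$chrom == ch]
      len <- min(lens[i], L - 1)
      s <- floor(stats::runif(1, 0, L - len))
      if (!length(occ_s[[ch]]) ||
          !any(pmin(s + len, occ_e[[ch]]) > pmax(s, occ_s[[ch]]))) {
        chrom[i] <- ch; start[i] <- s; used_len[i] <- len
        occ_s[[ch]] <- c(occ_s[[ch]], s)
        occ_e[[ch]] <- c(occ_e[[ch]], s + len)
        done <- TRUE
        break
      }
    }
    if (!done) {
      stop_cnvreg("could not place ", n, " non-overlapping loci on this ",
                  "genome; reduce n_loci or enlarge chromosomes")
    }
  }
  out <- data.frame(chrom = chrom, start = start, end = start + used_len,
                    stringsAsFactors = FALSE)
  out[sample.int(n), , drop = FALSE]      # decouple order from size
}

#' Simulate a pedigree-structured two-caller CNV call set
#'
#' Generates, deterministically for a given seed: a pedigree (breed
#' founders plus trio offspring), per-sample coverage, true CNV loci with
#' per-breed allele frequencies, Mendelian per-sample genotypes respecting
#' sex-chromosome ploidy, two callers' emitted call sets with the
#' configured noise, and gene/QTL annotation tracks (part of the genes and
#' QTL are planted inside true loci so overlap analyses have signal).
#'
#' Male X (and Y) genotypes are haploid: a single inherited allele, with
#' loss calls reported at copy number 0. Trio children inherit one allele
#' from each parent (X: sons draw only from the dam), so with noise-free
#' callers every child call is present in a parent.
#'
#' @param config A [sim_config()] object.
#' @param seed Integer seed; all randomness flows from it.
#' @return A `cnv_simulation` list: `genome`, `pedigree`, `trios`, `loci`
#'   (with per-breed allele-frequency columns), `genotypes` (allele-count
#'   matrix, loci x samples), `calls_primary` and `calls_support` (call
#'   data.frames carrying a bookkeeping `locus` column, `NA` for false
#'   positives), `genes`, `qtl`, `config`, `seed`.
#' @examples
#' sim <- simulate_cnv_data(sim_config(n_loci = 20), seed = 1)
#' head(sim$calls_primary)
#' @export
simulate_cnv_data <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "cnv_sim_config"))
  set.seed(seed)
  genome <- config$chromosomes
  breeds <- names(config$founders)

  ## pedigree: founders split male/female per breed, then trio children
  ped <- do.call(rbind, lapply(breeds, function(b) {
    n <- config$founders[[b]]
    data.frame(
      sample = sprintf("%s%03d", substr(b, 1, 1), seq_len(n)),
      sire = NA_character_, dam = NA_character_,
      sex = rep_len(c("male", "female"), n), breed = b,
      stringsAsFactors = FALSE)
  }))
  males <- ped$sample[ped$sex == "male"]
  females <- ped$sample[ped$sex == "female"]
  if (config$n_trios > min(length(males), length(females))) {
    stop_cnvreg("infeasible pedigree plan: need ", config$n_trios,
                " distinct sires and dams")
  }
  sires <- sample(males, config$n_trios)
  dams <- sample(females, config$n_trios)
  breed_of <- stats::setNames(ped$breed, ped$sample)
  kids <- data.frame(
    sample = sprintf("C%03d", seq_len(config$n_trios)),
    sire = sires, dam = dams,
    sex = sample(c("male", "female"), config$n_trios, replace = TRUE),
    breed = ifelse(breed_of[sires] == breed_of[dams],
                   breed_of[sires], "Composite"),
    stringsAsFactors = FALSE)
  ped <- rbind(ped, kids)
  ped$coverage <- pmin(pmax(
    stats::rgamma(nrow(ped), shape = config$cov_shape,
                  rate = config$cov_rate), 1), 31)
  ped <- validate_pedigree(ped)

  ## true loci
  lens <- pmin(pmax(round(stats::rlnorm(config$n_loci, config$len_meanlog,
                                        config$len_sdlog)),
                    config$min_locus_len), config$max_locus_len)
  loci <- place_intervals(config$n_loci, lens, genome)
  loci$locus_id <- sprintf("L%04d", seq_len(config$n_loci))
  loci$type <- ifelse(stats::runif(config$n_loci) < config$gain_frac,
                      "gain", "loss")
  af <- matrix(stats::rbeta(config$n_loci * length(breeds),
                            config$af_shape1, config$af_shape2),
               nrow = config$n_loci,
               dimnames = list(loci$locus_id, breeds))
  loci[paste0("af_", breeds)] <- af
  loci$category <- genome$category[match(loci$chrom, genome$chrom)]

  ## genotypes: allele counts per locus x sample, Mendelian for children
  geno <- matrix(0L, nrow = config$n_loci, ncol = nrow(ped),
                 dimnames = list(loci$locus_id, ped$sample))
  is_founder <- is.na(ped$sire)
  for (j in which(is_founder)) {
    f <- af[, breed_of[ped$sample[j]]]
    slots <- expected_ploidy(loci$category, ped$sex[j])
    geno[, j] <- stats::rbinom(config$n_loci, slots, f)
  }
  transmit <- function(parent_counts, parent_slots) {
    # draw one allele from a parent's slots (hypergeometric of 1)
    ifelse(parent_slots == 0, 0L,
           stats::rbinom(length(parent_counts), 1,
                         parent_counts / pmax(parent_slots, 1)))
  }
  for (j in which(!is_founder)) {
    sj <- match(ped$sire[j], ped$sample)
    dj <- match(ped$dam[j], ped$sample)
    cat_ <- loci$category
    from_dam <- transmit(geno[, dj], expected_ploidy(cat_, "female"))
    from_sire <- transmit(geno[, sj], expected_ploidy(cat_, "male"))
    child_slots <- expected_ploidy(cat_, ped$sex[j])
    g <- integer(config$n_loci)
    auto <- cat_ == "autosome"
    g[auto] <- from_dam[auto] + from_sire[auto]
    x <- cat_ == "X"
    if (ped$sex[j] == "female") {
      g[x] <- from_dam[x] + geno[x, sj]     # sire passes his whole X
    } else {
      g[x] <- from_dam[x]                   # son: maternal X only
    }
    y <- cat_ == "Y"
    g[y] <- if (ped$sex[j] == "male") geno[y, sj] else 0L
    geno[, j] <- pmin(g, child_slots)
  }

  ## emitted calls per caller
  emit_caller <- function(label) {
    idx <- which(geno >= 1, arr.ind = TRUE)
    if (nrow(idx)) {
      li <- idx[, 1]; sj <- idx[, 2]
      cov <- ped$coverage[sj]
      keep <- stats::runif(nrow(idx)) >= fn_prob(cov, config)
      li <- li[keep]; sj <- sj[keep]
      n <- length(li)
      ploidy <- expected_ploidy(loci$category[li], ped$sex[sj])
      cn <- ifelse(loci$type[li] == "loss",
                   pmax(ploidy - geno[cbind(li, sj)], 0),
                   ploidy + geno[cbind(li, sj)])
      s <- loci$start[li] + round(stats::rnorm(n, 0, config$jitter_sd))
      e <- loci$end[li] + round(stats::rnorm(n, 0, config$jitter_sd))
      L <- genome$length[match(loci$chrom[li], genome$chrom)]
      s <- pmax(s, 0); e <- pmin(e, L)
      bad <- s >= e
      s[bad] <- loci$start[li][bad]; e[bad] <- loci$end[li][bad]
      true_calls <- data.frame(
        chrom = loci$chrom[li], start = s, end = e,
        sample = ped$sample[sj], type = loci$type[li], cn = cn,
        caller = label, locus = loci$locus_id[li],
        stringsAsFactors = FALSE)
    } else {
      true_calls <- NULL
    }
    n_fp <- stats::rpois(1, config$fp_per_mb * sum(genome$length) / 1e6 *
                           nrow(ped))
    fp_calls <- NULL
    if (n_fp > 0) {
      fl <- pmin(pmax(round(stats::rlnorm(n_fp, config$len_meanlog,
                                          config$len_sdlog)),
                      config$min_locus_len), config$max_locus_len)
      ch <- sample(genome$chrom, n_fp, replace = TRUE,
                   prob = genome$length)
      L <- genome$length[match(ch, genome$chrom)]
      fl <- pmin(fl, L - 1)
      s <- floor(stats::runif(n_fp, 0, L - fl))
      who <- sample(ped$sample, n_fp, replace = TRUE)
      ty <- ifelse(stats::runif(n_fp) < config$gain_frac, "gain", "loss")
      pl <- expected_ploidy(
        genome$category[match(ch, genome$chrom)],
        ped$sex[match(who, ped$sample)])
      fp_calls <- data.frame(
        chrom = ch, start = s, end = s + fl, sample = who, type = ty,
        cn = ifelse(ty == "loss", pmax(pl - 1, 0), pl + 1),
        caller = label, locus = NA_character_, stringsAsFactors = FALSE)
      fp_calls <- fp_calls[pl > 0, , drop = FALSE]  # no calls on absent chromosomes
    }
    out <- rbind(true_calls, fp_calls)
    if (is.null(out)) return(NULL)
    out[order_intervals(out, "sample"), , drop = FALSE]
  }
  calls_a <- emit_caller("callerA")
  calls_b <- emit_caller("callerB")

  ## planted caller-concordant child false positives (validation knob)
  if (config$child_fp_prop > 0) {
    p <- config$child_fp_prop
    for (kid in kids$sample) {
      t_carried <- sum(geno[, kid] >= 1)
      n_fp <- round(p / (1 - p) * t_carried)
      if (n_fp == 0) next
      fl <- pmin(pmax(round(stats::rlnorm(n_fp, config$len_meanlog,
                                          config$len_sdlog)),
                      config$min_locus_len), config$max_locus_len)
      pos <- place_intervals(n_fp, fl, genome,
                             avoid = loci[, c("chrom", "start", "end")])
      sex <- ped$sex[match(kid, ped$sample)]
      pl <- expected_ploidy(genome$category[match(pos$chrom, genome$chrom)],
                            sex)
      shared <- data.frame(
        chrom = pos$chrom, start = pos$start, end = pos$end, sample = kid,
        type = "loss", cn = pmax(pl - 1, 0), caller = NA_character_,
        locus = NA_character_, stringsAsFactors = FALSE)
      shared <- shared[pl > 0, , drop = FALSE]
      a <- shared; a$caller <- "callerA"
      b <- shared; b$caller <- "callerB"
      calls_a <- rbind(calls_a, a)
      calls_b <- rbind(calls_b, b)
    }
    calls_a <- calls_a[order_intervals(calls_a, "sample"), , drop = FALSE]
    calls_b <- calls_b[order_intervals(calls_b, "sample"), , drop = FALSE]
  }

  ## annotation tracks: genes (some planted in loci) and QTL with traits
  n_planted <- round(config$n_genes * config$gene_planted_frac)
  host <- loci[sample(nrow(loci), n_planted, replace = TRUE), ]
  g_len <- pmax(200, round(stats::rlnorm(config$n_genes, log(2000), 0.8)))
  planted_start <- pmax(0, host$start +
    floor(stats::runif(n_planted, -0.25, 0.75) * (host$end - host$start)))
  rand_ch <- sample(genome$chrom, config$n_genes - n_planted,
                    replace = TRUE, prob = genome$length)
  rand_L <- genome$length[match(rand_ch, genome$chrom)]
  g_chrom <- c(host$chrom, rand_ch)
  g_start <- c(planted_start,
               floor(stats::runif(length(rand_ch), 0,
                                  rand_L - pmin(g_len[-seq_len(n_planted)],
                                                rand_L - 1))))
  g_end <- pmin(g_start + g_len,
                genome$length[match(g_chrom, genome$chrom)])
  genes <- data.frame(
    chrom = g_chrom, start = g_start, end = pmax(g_end, g_start + 1),
    feature_id = sprintf("G%04d", seq_len(config$n_genes)),
    class = sample(c("gene", "pseudogene", "ncRNA", "miscRNA"),
                   config$n_genes, replace = TRUE,
                   prob = c(0.65, 0.05, 0.2, 0.1)),
    label = "synthetic_gene", stringsAsFactors = FALSE)
  genes <- genes[order_intervals(genes), , drop = FALSE]

  q_len <- pmax(1000, round(stats::rlnorm(config$n_qtl, log(150000), 1)))
  q_ch <- sample(genome$chrom, config$n_qtl, replace = TRUE,
                 prob = genome$length)
  q_L <- genome$length[match(q_ch, genome$chrom)]
  q_len <- pmin(q_len, q_L - 1)
  q_s <- floor(stats::runif(config$n_qtl, 0, q_L - q_len))
  qtl <- data.frame(
    chrom = q_ch, start = q_s, end = q_s + q_len,
    feature_id = sprintf("Q%04d", seq_len(config$n_qtl)),
    class = "QTL",
    label = sample(sprintf("trait%02d", seq_len(config$n_traits)),
                   config$n_qtl, replace = TRUE),
    stringsAsFactors = FALSE)
  qtl <- qtl[order_intervals(qtl), , drop = FALSE]

  structure(list(
    genome = genome, pedigree = ped, trios = derive_trios(ped),
    loci = loci, genotypes = geno,
    calls_primary = calls_a, calls_support = calls_b,
    genes = genes, qtl = qtl, config = config, seed = seed),
    class = "cnv_simulation")
}

#' @export
print.cnv_simulation <- function(x, ...) {
  cat(sprintf(
    "Synthetic CNV survey (seed %d): %d samples (%d trios), %d loci on %d chromosomes\n",
    x$seed, nrow(x$pedigree), nrow(x$trios), nrow(x$loci), nrow(x$genome)))
  cat(sprintf("  caller A: %d calls; caller B: %d calls\n",
              nrow(x$calls_primary), nrow(x$calls_support)))
  invisible(x)
}

#' Write a simulated data set to disk
#'
#' Emits the files the pipeline readers consume: `genome.tsv`,
#' `pedigree.tsv`, `calls_callerA.tsv`, `calls_callerB.tsv`, `genes.bed`,
#' `qtl.bed`, and `truth_loci.bed`.
#'
#' @param sim A `cnv_simulation` object.
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(sim$genome, file.path(dir, "genome.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_pedigree(sim$pedigree, file.path(dir, "pedigree.tsv"))
  write_calls(sim$calls_primary, file.path(dir, "calls_callerA.tsv"))
  write_calls(sim$calls_support, file.path(dir, "calls_callerB.tsv"))
  write_features(sim$genes, file.path(dir, "genes.bed"))
  write_features(sim$qtl, file.path(dir, "qtl.bed"))
  truth <- data.frame(chrom = sim$loci$chrom, start = sim$loci$start,
                      end = sim$loci$end, feature_id = sim$loci$locus_id,
                      class = "truth_locus", label = sim$loci$type,
                      stringsAsFactors = FALSE)
  write_features(truth, file.path(dir, "truth_loci.bed"))
  invisible(dir)
}

#' Precision and recall of CNVR recovery against simulation truth
#'
#' A segregating truth locus (one with at least one carrier) counts as
#' recovered when some CNVR reciprocally overlaps it by at least
#' `reciprocal`; a CNVR counts as a true discovery under the same
#' criterion.
#'
#' @param cnvrs CNVR data.frame from the pipeline.
#' @param sim The `cnv_simulation` the calls came from.
#' @param reciprocal Reciprocal-overlap threshold for matching (default
#'   0.5).
#' @return A list: `recall`, `precision`, `n_truth` (segregating loci),
#'   `n_cnvr`.
#' @export
evaluate_against_truth <- function(cnvrs, sim, reciprocal = 0.5) {
  seg <- sim$loci[rowSums(sim$genotypes >= 1) > 0, , drop = FALSE]
  match_any <- function(q, targets) {
    ti <- which(targets$chrom == q$chrom)
    if (!length(ti)) return(FALSE)
    ov <- ov_bp(q$start, q$end, targets$start[ti], targets$end[ti])
    any(pmin(ov / (q$end - q$start),
             ov / (targets$end[ti] - targets$start[ti])) >= reciprocal)
  }
  recovered <- vapply(seq_len(nrow(seg)), function(i)
    match_any(seg[i, ], cnvrs), logical(1))
  true_pos <- vapply(seq_len(nrow(cnvrs)), function(i)
    match_any(cnvrs[i, ], seg), logical(1))
  list(recall = if (nrow(seg)) mean(recovered) else NA_real_,
       precision = if (nrow(cnvrs)) mean(true_pos) else NA_real_,
       n_truth = nrow(seg), n_cnvr = nrow(cnvrs))
}
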