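# Builders and independent oracles shared across test files.

mk_calls <- function(start, end, chrom = "chr1", sample = "s1",
                     type = "loss", cn = NA_real_, caller = "A") {
  data.frame(chrom = chrom, start = start, end = end, sample = sample,
             type = type, cn = cn, caller = caller, stringsAsFactors = FALSE)
}

tiny_genome <- function() {
  data.frame(chrom = c("chr1", "chr2", "chrX"),
             length = c(1e6, 5e5, 4e5),
             category = c("autosome", "autosome", "X"),
             stringsAsFactors = FALSE)
}

mk_pedigree <- function(samples, sire = NA, dam = NA, sex = "male",
                        breed = "Duroc", coverage = 10) {
  data.frame(sample = samples, sire = sire, dam = dam,
             sex = rep_len(sex, length(samples)),
             breed = rep_len(breed, length(samples)),
             coverage = rep_len(coverage, length(samples)),
             stringsAsFactors = FALSE)
}

# Minimal CNVR table from explicit carrier lists (for functions that only
# need spans + carriers).
mk_cnvrs <- function(start, end, carriers, chrom = "chr1", type = "loss") {
  df <- data.frame(chrom = rep_len(chrom, length(start)), start = start,
                   end = end,
                   cnvr_id = sprintf("CNVR%04d", seq_along(start)),
                   type = rep_len(type, length(start)),
                   frequency = lengths(carriers),
                   n_members = lengths(carriers), stringsAsFactors = FALSE)
  df$carriers <- carriers
  df$member_idx <- as.list(seq_along(start))
  df
}

# O(n*m) all-pairs reference for the consensus filter.
brute_consensus <- function(primary, support, frac = 0.10,
                            match_type = FALSE) {
  keep <- vapply(seq_len(nrow(primary)), function(i) {
    any(vapply(seq_len(nrow(support)), function(j) {
      if (primary$sample[i] != support$sample[j]) return(FALSE)
      if (primary$chrom[i] != support$chrom[j]) return(FALSE)
      if (match_type && primary$type[i] != support$type[j]) return(FALSE)
      ov <- max(0, min(primary$end[i], support$end[j]) -
                   max(primary$start[i], support$start[j]))
      ov / (primary$end[i] - primary$start[i]) >= frac
    }, logical(1)))
  }, logical(1))
  primary[keep, , drop = FALSE]
}

# Partition of call indices into CNVRs as a canonical sorted signature.
partition_signature <- function(cnvrs, key) {
  unname(sort(vapply(cnvrs$member_idx,
                     function(m) paste(sort(key[m]), collapse = ","), "")))
}

# igraph-based reference for reciprocal-overlap connected components.
brute_components <- function(calls, frac = 0.5) {
  n <- nrow(calls)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j || calls$chrom[i] != calls$chrom[j]) next
    ov <- max(0, min(calls$end[i], calls$end[j]) -
                 max(calls$start[i], calls$start[j]))
    ro <- min(ov / (calls$end[i] - calls$start[i]),
              ov / (calls$end[j] - calls$start[j]))
    adj[i, j] <- adj[j, i] <- ro >= frac
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::components(g)$membership
}

# Exhaustive hypergeometric enumeration for the two-sided Fisher p-value.
fisher_enum <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  xs <- max(0, c1 - r2):min(r1, c1)
  pr <- choose(r1, xs) * choose(r2, c1 - xs) / choose(n, c1)
  p_obs <- pr[xs == a]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}
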