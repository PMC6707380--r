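test_that("within-sample merge unions overlapping same-type calls only", {
  merged <- merge_within_sample(mk_calls(c(0, 50), c(100, 150), cn = c(1, 1)))
  expect_equal(nrow(merged), 1)
  expect_equal(c(merged$start, merged$end), c(0, 150))
  expect_equal(merged$type, "loss")
  # types differ: both kept unchanged
  two <- rbind(mk_calls(0, 100), mk_calls(50, 150, type = "gain"))
  expect_equal(nrow(merge_within_sample(two)), 2)
  # touching calls do not merge
  touch <- mk_calls(c(0, 100), c(100, 200))
  expect_equal(nrow(merge_within_sample(touch)), 2)
  single <- mk_calls(5, 50)
  expect_equal(merge_within_sample(single), single)
  expect_error(merge_within_sample(mk_calls(c(0, 0), c(10, 10),
                                            sample = c("a", "b"))),
               "single sample")
})

test_that("merged copy number is the length-weighted member mean", {
  m <- merge_within_sample(mk_calls(c(0, 100), c(200, 300), cn = c(1, 4)))
  # weights 200 bp at cn 1 overlapping... lengths 200 and 200 -> mean 2.5
  expect_equal(m$cn, (1 * 200 + 4 * 200) / 400)
  m2 <- merge_within_sample(mk_calls(c(0, 100), c(200, 300),
                                     cn = c(1, NA)))
  expect_true(is.na(m2$cn))
})

test_that("a<c<b<d pair with sufficient reciprocal overlap merges to [a,d]", {
  calls <- mk_calls(c(0, 40), c(100, 140), sample = c("s1", "s2"))
  cn <- build_cnvrs(calls)
  expect_equal(nrow(cn), 1)
  expect_equal(c(cn$start, cn$end), c(0, 140))
  expect_setequal(cn$carriers[[1]], c("s1", "s2"))
  # chaining: (1,3) fail pairwise but (2,3) pass -> one component
  calls3 <- mk_calls(c(0, 40, 90), c(100, 140, 190),
                     sample = c("s1", "s2", "s3"))
  cn3 <- build_cnvrs(calls3)
  expect_equal(nrow(cn3), 1)
  expect_equal(c(cn3$start, cn3$end), c(0, 190))
  # clique semantics refuses the chain
  cq <- build_cnvrs(calls3, semantics = "clique")
  expect_equal(nrow(cq), 2)
  # disjoint calls stay separate
  expect_equal(nrow(build_cnvrs(mk_calls(c(0, 5000), c(100, 5100),
                                         sample = c("s1", "s2")))), 2)
})

test_that("component merging matches an igraph brute-force oracle and is order-free", {
  skip_if_not_installed("igraph")
  set.seed(202)
  for (rep in 1:8) {
    n <- 150
    s <- sample.int(30000, n, replace = TRUE)
    calls <- mk_calls(s, s + sample.int(2000, n, replace = TRUE),
                      chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                      sample = paste0("s", sample.int(20, n, replace = TRUE)))
    calls$key <- paste0(calls$chrom, ":", calls$start, "-", calls$end,
                        "@", calls$sample, "#", seq_len(n))
    cn <- build_cnvrs(calls)
    # partition: every call in exactly one CNVR
    expect_setequal(unlist(cn$member_idx), seq_len(n))
    ref <- brute_components(calls, 0.5)
    ref_sig <- unname(sort(vapply(split(calls$key, ref),
                           function(k) paste(sort(k), collapse = ","), "")))
    expect_equal(partition_signature(cn, calls$key), ref_sig)
    # permuting input order yields the identical CNVR set
    perm <- sample.int(n)
    cn2 <- build_cnvrs(calls[perm, ])
    expect_equal(cn[c("chrom", "start", "end", "cnvr_id", "type",
                      "frequency", "n_members")],
                 cn2[c("chrom", "start", "end", "cnvr_id", "type",
                       "frequency", "n_members")])
    # raising the reciprocal threshold never decreases the CNVR count
    expect_gte(nrow(build_cnvrs(calls, cnv_thresholds(reciprocal_frac = 0.8))),
               nrow(cn))
  }
})

test_that("CNVR spans, carriers, and ids follow member bookkeeping", {
  calls <- mk_calls(c(0, 40, 10000), c(100, 140, 10500),
                    sample = c("s1", "s2", "s1"),
                    type = c("loss", "gain", "loss"))
  cn <- build_cnvrs(calls)
  expect_equal(cn$cnvr_id, c("CNVR0001", "CNVR0002"))
  expect_equal(cn$type, c("mixed", "loss"))
  for (i in seq_len(nrow(cn))) {
    m <- cn$member_idx[[i]]
    expect_equal(cn$start[i], min(calls$start[m]))
    expect_equal(cn$end[i], max(calls$end[m]))
    expect_setequal(cn$carriers[[i]], unique(calls$sample[m]))
    expect_equal(cn$frequency[i], length(unique(calls$sample[m])))
  }
})

test_that("type assignment distinguishes pure and mixed regions", {
  expect_equal(assign_type(c("loss", "loss")), "loss")
  expect_equal(assign_type(c("loss", "gain")), "mixed")
  expect_equal(assign_type("gain"), "gain")
  expect_error(assign_type(character()), "at least one")
})

test_that("length filter removes strictly-below-minimum regions", {
  cn <- mk_cnvrs(c(0, 1000, 5000), c(199, 1200, 403900),
                 carriers = list("s1", "s2", "s3"))
  kept <- filter_min_length(cn, cnv_thresholds(min_cnvr_len = 200))
  expect_equal(kept$end - kept$start, c(200, 398900))
})

test_that("presence matrix row and column sums are consistent", {
  cn <- mk_cnvrs(c(0, 1000), c(500, 1600),
                 carriers = list(c("s1", "s3"), "s2"))
  m <- cnvr_presence(cn, c("s1", "s2", "s3"))
  expect_equal(unname(m[1, ]), c(1L, 0L, 1L))
  expect_equal(unname(rowSums(m)), cn$frequency)
  expect_error(cnvr_presence(cn, c("s1", "s2")), "s3")
  empty <- cn[0, ]
  expect_equal(dim(cnvr_presence(empty, "s1")), c(0L, 1L))
})

test_that("per-sample counts from presence columns match direct recounts", {
  set.seed(33)
  n <- 60
  s <- sample.int(50000, n)
  calls <- mk_calls(s, s + sample.int(800, n, replace = TRUE),
                    sample = paste0("s", sample.int(6, n, replace = TRUE)))
  cn <- build_cnvrs(merge_within_samples(calls))
  pres <- cnvr_presence(cn, paste0("s", 1:6))
  direct <- vapply(paste0("s", 1:6), function(x)
    sum(vapply(cn$carriers, function(cc) x %in% cc, logical(1))), numeric(1))
  expect_equal(colSums(pres), direct)
})
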