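mk_features <- function(start, end, chrom = "chr1", id = NULL,
                        class = "gene", label = ".") {
  data.frame(chrom = rep_len(chrom, length(start)), start = start, end = end,
             feature_id = id %||% sprintf("F%03d", seq_along(start)),
             class = rep_len(class, length(start)),
             label = rep_len(label, length(start)), stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("feature overlap uses the 1 bp rule on half-open coordinates", {
  cn <- mk_cnvrs(100, 200, carriers = list("s1"))
  expect_equal(nrow(overlap_features(cn, mk_features(199, 250))), 1)
  expect_equal(nrow(overlap_features(cn, mk_features(200, 250))), 0)
  two <- overlap_features(cn, mk_features(c(120, 180), c(140, 260)))
  expect_equal(nrow(two), 2)
  roll <- overlap_rollup(two)
  expect_equal(roll$n_cnvrs_overlapped, 1)
  expect_equal(roll$n_features_overlapped, 2)
  expect_error(
    overlap_features(cn, mk_features(0, 10, chrom = "chrZ"),
                     genome = tiny_genome()),
    "chrZ")
})

test_that("feature overlap matches a brute-force all-pairs scan", {
  set.seed(55)
  n <- 80; m <- 200
  s1 <- sample.int(50000, n); s2 <- sample.int(50000, m)
  cn <- mk_cnvrs(s1, s1 + sample.int(2000, n, replace = TRUE),
                 carriers = as.list(paste0("s", seq_len(n))),
                 chrom = sample(c("chr1", "chr2"), n, replace = TRUE))
  fx <- mk_features(s2, s2 + sample.int(1500, m, replace = TRUE),
                    chrom = sample(c("chr1", "chr2"), m, replace = TRUE))
  got <- overlap_features(cn, fx)
  ref <- do.call(rbind, lapply(seq_len(n), function(i) {
    hits <- which(fx$chrom == cn$chrom[i] &
                    pmin(fx$end, cn$end[i]) - pmax(fx$start, cn$start[i]) >= 1)
    if (!length(hits)) return(NULL)
    data.frame(cnvr_id = cn$cnvr_id[i], feature_id = fx$feature_id[hits])
  }))
  expect_setequal(paste(got$cnvr_id, got$feature_id),
                  paste(ref$cnvr_id, ref$feature_id))
  expect_true(all(got$overlap_bp >= 1))
})

test_that("breed-specific CNVRs have single-breed carrier sets", {
  ped <- mk_pedigree(c("d1", "d2", "l1"), breed = c("Duroc", "Duroc", "Landrace"))
  cn <- mk_cnvrs((0:2) * 10000, (0:2) * 10000 + 500,
                 carriers = list(c("d1", "d2"), c("d1", "l1"), "l1"))
  bs <- breed_specific(cn, ped)
  expect_equal(nrow(bs), 2)
  expect_equal(bs$breed, c("Duroc", "Landrace"))
  expect_equal(bs$single_carrier, c(FALSE, TRUE))
  expect_equal(attr(bs, "prop_single_carrier"), 0.5)
  # subsets across breeds are disjoint and within the full set
  expect_true(all(bs$cnvr_id %in% cn$cnvr_id))
  expect_equal(anyDuplicated(bs$cnvr_id), 0)
  expect_error(breed_specific(cn, ped[-3, ]), "without breed")
})

test_that("external comparison counts shared-base overlaps with printed rounding", {
  cn <- mk_cnvrs((0:3) * 10000, (0:3) * 10000 + 500,
                 carriers = as.list(paste0("s", 1:4)))
  ext <- mk_features(c(400, 20400), c(600, 20600))
  cmp <- compare_external(cn, ext)
  expect_equal(cmp$n_overlapped, 2)
  expect_equal(cmp$ratio_pct, 50.00)
  none <- compare_external(cn, mk_features(900000, 900100))
  expect_equal(none$n_overlapped, 0)
  expect_equal(none$ratio_pct, 0)
  expect_error(compare_external(cn, ext[0, ]), "empty")
})
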