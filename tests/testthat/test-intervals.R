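test_that("overlap arithmetic follows half-open coordinates", {
  expect_equal(overlap_bp(interval("chr1", 100, 200),
                          interval("chr1", 150, 250)), 50)
  # touching intervals share no base
  expect_equal(overlap_bp(interval("chr1", 100, 200),
                          interval("chr1", 200, 300)), 0)
  expect_equal(overlap_bp(interval("chr1", 0, 100),
                          interval("chr1", 0, 100)), 100)
  expect_equal(overlap_bp(interval("chr1", 0, 100),
                          interval("chr2", 0, 100)), 0)
  expect_error(interval("chr1", 200, 200), "start < end")
  expect_error(interval("chr1", -5, 10), "start < end")
})

test_that("overlap_fraction is asymmetric and reciprocal_overlap symmetric", {
  q <- interval("chr1", 1000, 2000); t <- interval("chr1", 1900, 3000)
  expect_equal(overlap_fraction(q, t), 0.10)
  expect_equal(overlap_fraction(t, q), 100 / 1100)
  expect_equal(overlap_fraction(q, q), 1.0)
  expect_equal(overlap_fraction(interval("chr1", 0, 10),
                                interval("chr1", 500, 600)), 0)
  expect_equal(reciprocal_overlap(interval("chr1", 0, 100),
                                  interval("chr1", 40, 140)), 0.6)
  expect_equal(reciprocal_overlap(interval("chr1", 0, 100),
                                  interval("chr1", 0, 1000)), 0.1)
  expect_equal(reciprocal_overlap(q, q), 1.0)
})

test_that("overlap identities hold on random interval pairs", {
  set.seed(42)
  for (rep in 1:200) {
    s <- sort(sample.int(1000, 4, replace = TRUE) - 1)
    i1 <- interval("chr1", s[1], s[3] + 1)
    i2 <- interval("chr1", s[2], s[4] + 1)
    ob <- overlap_bp(i1, i2)
    expect_equal(ob, overlap_bp(i2, i1))
    expect_lte(ob, min(i1$end - i1$start, i2$end - i2$start))
    expect_lte(reciprocal_overlap(i1, i2), overlap_fraction(i1, i2))
  }
})

test_that("union_length matches a per-base bitmap oracle", {
  expect_equal(union_length(interval("chr1", c(0, 50, 200),
                                     c(100, 150, 300))), 250)
  expect_equal(union_length(interval(character(), numeric(), numeric())), 0)
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(1:30, 1)
    chrom <- sample(c("c1", "c2"), n, replace = TRUE)
    s <- sample.int(9999, n, replace = TRUE) - 1
    len <- sample.int(500, n, replace = TRUE)
    iv <- interval(chrom, s, pmin(s + len, 10000))
    bitmap <- sum(vapply(c("c1", "c2"), function(ch) {
      covered <- logical(10000)
      d <- iv[iv$chrom == ch, , drop = FALSE]
      for (i in seq_len(nrow(d))) {
        covered[(d$start[i] + 1):d$end[i]] <- TRUE
      }
      sum(covered)
    }, numeric(1)))
    expect_equal(union_length(iv), bitmap)
  }
})

test_that("union_length is order-invariant, split-invariant, and agrees with IRanges", {
  skip_if_not_installed("IRanges")
  set.seed(11)
  s <- sample.int(1e6, 50); e <- s + sample.int(5000, 50)
  iv <- interval("chr1", s, e)
  expect_equal(union_length(iv), union_length(iv[sample.int(50), ]))
  # split one interval into adjacent pieces
  mid <- floor((s[1] + e[1]) / 2)
  split_iv <- rbind(interval("chr1", s[1], mid), interval("chr1", mid, e[1]),
                    iv[-1, ])
  expect_equal(union_length(split_iv), union_length(iv))
  ir <- IRanges::reduce(IRanges::IRanges(start = s + 1, end = e))
  expect_equal(union_length(iv), sum(IRanges::width(ir)))
})

test_that("expected ploidy reflects chromosome category and sex", {
  expect_equal(expected_ploidy("autosome", c("male", "female")), c(2L, 2L))
  expect_equal(expected_ploidy("X", c("male", "female")), c(1L, 2L))
  expect_equal(expected_ploidy("Y", c("male", "female")), c(1L, 0L))
})
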