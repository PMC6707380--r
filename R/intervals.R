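#' Pipeline thresholds
#'
#' Bundle of the cutoffs that drive the CNVR pipeline. Defaults follow the
#' standard two-caller survey design: a call on one caller must be at least
#' 10% covered by a single call from the second caller to be retained;
#' calls merge across samples at >= 50% reciprocal overlap; merged regions
#' shorter than 200 bp are discarded; annotation overlap counts from a
#' single shared base.
#'
#' @param support_frac Minimum one-way overlap fraction of a primary call
#'   by one support call (proportion in (0, 1]).
#' @param reciprocal_frac Minimum pairwise reciprocal overlap for
#'   cross-sample merging (proportion in (0, 1]).
#' @param min_cnvr_len Minimum CNVR length kept, in bp (regions strictly
#'   shorter are removed).
#' @param min_feature_overlap Minimum shared bp for a CNVR/feature overlap.
#' @return An object of class `cnv_thresholds`.
#' @examples
#' cnv_thresholds()
#' cnv_thresholds(reciprocal_frac = 0.9)
#' @export
cnv_thresholds <- function(support_frac = 0.10, reciprocal_frac = 0.50,
                           min_cnvr_len = 200, min_feature_overlap = 1) {
  for (p in c(support_frac, reciprocal_frac)) {
    if (!is.numeric(p) || length(p) != 1 || p <= 0 || p > 1) {
      stop_cnvreg("overlap fractions must be single proportions in (0, 1]")
    }
  }
  if (min_cnvr_len < 1 || min_feature_overlap < 1) {
    stop_cnvreg("minimum lengths must be >= 1 bp")
  }
  structure(
    list(support_frac = support_frac, reciprocal_frac = reciprocal_frac,
         min_cnvr_len = as.integer(min_cnvr_len),
         min_feature_overlap = as.integer(min_feature_overlap)),
    class = "cnv_thresholds")
}

#' @export
print.cnv_thresholds <- function(x, ...) {
  cat("CNVR pipeline thresholds:\n")
  cat(sprintf("  support overlap fraction : >= %g\n", x$support_frac))
  cat(sprintf("  reciprocal overlap       : >= %g\n", x$reciprocal_frac))
  cat(sprintf("  minimum CNVR length      : %d bp\n", x$min_cnvr_len))
  cat(sprintf("  feature overlap minimum  : %d bp\n", x$min_feature_overlap))
  invisible(x)
}

#' Construct a table of genomic intervals
#'
#' All coordinates in the package are 0-based half-open (`[start, end)`),
#' the BED convention native to CNV caller output. Validation enforces
#' `0 <= start < end` and, when genome metadata is supplied, containment
#' within the chromosome.
#'
#' @param chrom Chromosome names.
#' @param start,end 0-based half-open coordinates (start inclusive, end
#'   exclusive), recycled to a common length.
#' @return A data.frame with columns `chrom`, `start`, `end`.
#' @examples
#' interval("chr1", c(0, 500), c(100, 900))
#' @export
interval <- function(chrom, start, end) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df, genome = NULL, what = "interval") {
  req <- c("chrom", "start", "end")
  if (!all(req %in% names(df))) {
    stop_cnvreg(what, " table must have columns chrom, start, end")
  }
  bad <- which(!is.finite(df$start) | !is.finite(df$end) |
                 df$start < 0 | df$start >= df$end)
  if (length(bad)) {
    stop_cnvreg("invalid ", what, " coordinates (need 0 <= start < end) at row",
                if (length(bad) > 1) "s " else " ",
                paste(utils::head(bad, 5), collapse = ", "))
  }
  if (!is.null(genome)) {
    unknown <- setdiff(unique(df$chrom), genome$chrom)
    if (length(unknown)) {
      stop_cnvreg(what, " on chromosome(s) absent from genome metadata: ",
                  paste(unknown, collapse = ", "))
    }
    len <- genome$length[match(df$chrom, genome$chrom)]
    over <- which(df$end > len)
    if (length(over)) {
      stop_cnvreg(what, " extends past chromosome end at row ",
                  paste(utils::head(over, 5), collapse = ", "))
    }
  }
  invisible(df)
}

# Vectorised half-open overlap in bp for same-chromosome coordinates.
ov_bp <- function(s1, e1, s2, e2) pmax(0, pmin(e1, e2) - pmax(s1, s2))

#' Overlap, overlap fraction, and reciprocal overlap of intervals
#'
#' `overlap_bp()` returns the number of shared bases of two intervals
#' (0 when they sit on different chromosomes, touch end-to-start, or are
#' disjoint). `overlap_fraction()` divides the shared bases by the length
#' of the *query* interval, so it is asymmetric; it is the criterion used
#' for caller-support filtering. `reciprocal_overlap()` takes the minimum
#' of the two one-way fractions, the symmetric similarity used for
#' cross-sample CNVR merging.
#'
#' Arguments are interval tables as built by [interval()]; rows are paired
#' elementwise, with single-row tables recycled.
#'
#' @param i1,i2,query,target Interval data.frames (`chrom`, `start`, `end`).
#' @return A numeric vector: bp for `overlap_bp()`, proportions in
#'   `[0, 1]` for the other two.
#' @examples
#' overlap_bp(interval("chr1", 100, 200), interval("chr1", 150, 250))  # 50
#' overlap_fraction(interval("chr1", 1000, 2000), interval("chr1", 1900, 3000))
#' reciprocal_overlap(interval("chr1", 0, 100), interval("chr1", 40, 140))
#' @export
overlap_bp <- function(i1, i2) {
  validate_intervals(i1)
  validate_intervals(i2)
  n <- max(nrow(i1), nrow(i2))
  if (nrow(i1) == 1) i1 <- i1[rep(1, n), ]
  if (nrow(i2) == 1) i2 <- i2[rep(1, n), ]
  if (nrow(i1) != nrow(i2)) {
    stop_cnvreg("interval tables must have equal row counts (or one row)")
  }
  ifelse(i1$chrom == i2$chrom, ov_bp(i1$start, i1$end, i2$start, i2$end), 0)
}

#' @rdname overlap_bp
#' @export
overlap_fraction <- function(query, target) {
  overlap_bp(query, target) / rep(query$end - query$start,
                                  length.out = max(nrow(query), nrow(target)))
}

#' @rdname overlap_bp
#' @export
reciprocal_overlap <- function(i1, i2) {
  pmin(overlap_fraction(i1, i2), overlap_fraction(i2, i1))
}

#' Total bases covered by a set of intervals
#'
#' Length of the per-chromosome union, i.e. bases covered by at least one
#' interval, counted once.
#'
#' @param intervals Interval data.frame (`chrom`, `start`, `end`); may be
#'   empty.
#' @return Total unique bp (a single number).
#' @examples
#' union_length(interval("chr1", c(0, 50, 200), c(100, 150, 300)))  # 250
#' @export
union_length <- function(intervals) {
  if (nrow(intervals) == 0) return(0)
  validate_intervals(intervals)
  sum(vapply(split(intervals, intervals$chrom), function(d) {
    o <- order(d$start, d$end)
    s <- d$start[o]; e <- d$end[o]
    tot <- 0; cur_s <- s[1]; cur_e <- e[1]
    for (i in seq_along(s)[-1]) {
      if (s[i] > cur_e) {          # gap: close the current run
        tot <- tot + (cur_e - cur_s)
        cur_s <- s[i]; cur_e <- e[i]
      } else if (e[i] > cur_e) {
        cur_e <- e[i]
      }
    }
    tot + (cur_e - cur_s)
  }, numeric(1)))
}
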