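## Enrichment statistics: Fisher's exact trait enrichment over QTL-CNVR
## overlap and binomial term overrepresentation, both with
## Benjamini-Hochberg correction.

#' Fisher's exact test p-value for a 2x2 table
#'
#' Thin, validated wrapper around [stats::fisher.test()]. The two-sided
#' p-value follows the usual convention of summing, at fixed margins, the
#' hypergeometric probabilities of all tables no more probable than the
#' observed one.
#'
#' @param a,b,c,d Non-negative integer cell counts, laid out as rows
#'   `(a, b)` / `(c, d)`.
#' @param alternative `"two.sided"` (default), `"greater"`, or `"less"`
#'   (in terms of the odds ratio).
#' @return The p-value.
#' @examples
#' fisher_exact(5, 0, 0, 5)  # 2/252
#' @export
fisher_exact <- function(a, b, c, d,
                         alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  x <- c(a, b, c, d)
  if (any(!is.finite(x) | x < 0 | x != round(x))) {
    stop_cnvreg("cell counts must be non-negative integers")
  }
  if (sum(x) == 0) stop_cnvreg("degenerate 2x2 table: all margins empty")
  stats::fisher.test(matrix(x, nrow = 2, byrow = TRUE),
                     alternative = alternative)$p.value
}

odds_ratio <- function(a, b, c, d) {
  ifelse(b * c == 0, ifelse(a * d == 0, NA_real_, Inf), (a * d) / (b * c))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment via [stats::p.adjust()], with input validation;
#' results are returned in input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop_cnvreg("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' QTL trait enrichment among CNVR-overlapped QTL
#'
#' Each QTL record is flagged as overlapped when it shares at least
#' `min_feature_overlap` bp with some CNVR. For every trait with at least
#' one overlapped QTL, a 2x2 table contrasts that trait's QTL against all
#' other traits' QTL, split by overlapped status:
#' `(a, b; c, d) = (trait overlapped, trait not; other overlapped, other
#' not)`. Two-sided Fisher p-values are BH-corrected across that trait
#' family. QTL records are counted as records (not deduplicated by
#' interval).
#'
#' @param cnvrs CNVR data.frame.
#' @param qtl Feature data.frame of QTL records; `label` holds the trait
#'   name.
#' @param thresholds A [cnv_thresholds()].
#' @param alpha Significance level on the adjusted p-value (default 0.05).
#' @param alternative Passed to [fisher_exact()].
#' @return A data.frame, one row per tested trait, ranked by overlap count
#'   then adjusted p: `trait`, `a`, `b`, `c`, `d`, `odds_ratio`, `p`,
#'   `p_adj`, `significant`.
#' @export
qtl_enrichment <- function(cnvrs, qtl, thresholds = cnv_thresholds(),
                           alpha = 0.05, alternative = "two.sided") {
  if (any(is.na(qtl$label) | qtl$label == "." | qtl$label == "")) {
    stop_cnvreg("every QTL record needs a trait label")
  }
  pairs <- overlap_features(cnvrs, qtl, thresholds)
  qtl$overlapped <- qtl$feature_id %in% pairs$feature_id
  n_ov <- sum(qtl$overlapped); n_tot <- nrow(qtl)
  per_trait <- split(qtl$overlapped, qtl$label)
  tested <- names(per_trait)[vapply(per_trait, any, logical(1))]
  if (!length(tested)) {
    warning("no trait has an overlapped QTL; nothing to test", call. = FALSE)
    return(data.frame(trait = character(), a = integer(), b = integer(),
                      c = integer(), d = integer(), odds_ratio = numeric(),
                      p = numeric(), p_adj = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, lapply(tested, function(t) {
    ov <- per_trait[[t]]
    a <- sum(ov); b <- length(ov) - a
    c_ <- n_ov - a; d_ <- (n_tot - length(ov)) - c_
    data.frame(trait = t, a = a, b = b, c = c_, d = d_,
               odds_ratio = odds_ratio(a, b, c_, d_),
               p = fisher_exact(a, b, c_, d_, alternative),
               stringsAsFactors = FALSE)
  }))
  res$p_adj <- bh_adjust(res$p)
  res$significant <- res$p_adj < alpha
  res <- res[order(-res$a, res$p_adj, res$trait), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Binomial test of term overrepresentation
#'
#' For a study gene set drawn from a gene universe and a mapping of
#' annotation terms to genes, each term is tested one-sided for excess
#' membership: with `k` study genes in the term, `n` study genes total and
#' background proportion `p0 = |term| / |universe|`, the p-value is
#' `P(X >= k)` under `Binomial(n, p0)`. Terms with `k >= 1` form the BH
#' correction family.
#'
#' @param study Character vector of study gene ids (subset of `universe`).
#' @param terms Named list mapping term label to character vector of gene
#'   ids (each a subset of `universe`).
#' @param universe Character vector of all gene ids.
#' @param alpha Significance level on the adjusted p-value.
#' @return A data.frame, one row per tested term: `term`, `k`, `n`, `p0`,
#'   `expected`, `fold`, `p`, `p_adj`, `significant`, ordered by adjusted
#'   p.
#' @export
binomial_overrep <- function(study, terms, universe, alpha = 0.05) {
  universe <- unique(universe)
  if (!length(universe)) stop_cnvreg("empty gene universe")
  study <- unique(study)
  if (length(setdiff(study, universe))) {
    stop_cnvreg("study set contains genes outside the universe")
  }
  n <- length(study)
  res <- do.call(rbind, lapply(names(terms), function(t) {
    tg <- intersect(unique(terms[[t]]), universe)
    k <- length(intersect(study, tg))
    p0 <- length(tg) / length(universe)
    data.frame(term = t, k = k, n = n, p0 = p0, expected = n * p0,
               fold = if (p0 > 0) (k / n) / p0 else NA_real_,
               p = stats::pbinom(k - 1, n, p0, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  res <- res[res$k >= 1, , drop = FALSE]
  res$p_adj <- bh_adjust(res$p)
  res$significant <- res$p_adj < alpha
  res <- res[order(res$p_adj, res$p, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}
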