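## Descriptive statistics of a CNVR set: per-chromosome distribution,
## genome coverage, size/frequency spectra, and correlations.

#' Per-chromosome CNVR distribution
#'
#' One row per chromosome of the genome (including chromosomes without
#' CNVRs): CNVR count, unique bp covered, and the covered ratio. Also
#' reports the unweighted mean of the per-chromosome ratios and the
#' Pearson correlation between chromosome length and CNVR count.
#'
#' @param cnvrs CNVR data.frame.
#' @param genome Genome metadata data.frame.
#' @return A list: `table` (per-chromosome data.frame with `chrom`,
#'   `length`, `n_cnvr`, `unique_bp`, `ratio`, `ratio_pct`), `mean_ratio`,
#'   `mean_ratio_pct`, `r_length_count`.
#' @export
chromosome_summary <- function(cnvrs, genome) {
  genome <- validate_genome(genome)
  if (nrow(cnvrs)) validate_intervals(cnvrs, genome, what = "CNVR")
  tab <- data.frame(
    chrom = genome$chrom, length = genome$length,
    n_cnvr = vapply(genome$chrom,
                    function(ch) sum(cnvrs$chrom == ch), numeric(1)),
    unique_bp = vapply(genome$chrom, function(ch)
      union_length(cnvrs[cnvrs$chrom == ch, , drop = FALSE]), numeric(1)),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  summarize_chromosome_table(tab)
}

#' @rdname chromosome_summary
#' @param table Data.frame with columns `chrom`, `length`, `n_cnvr`,
#'   `unique_bp` (e.g. a published distribution table), from which the
#'   ratios and correlations are recomputed.
#' @export
summarize_chromosome_table <- function(table) {
  req <- c("chrom", "length", "n_cnvr", "unique_bp")
  if (!all(req %in% names(table))) {
    stop_cnvreg("table needs columns: ", paste(req, collapse = ", "))
  }
  if (any(table$unique_bp > table$length)) {
    stop_cnvreg("unique covered bp exceeds chromosome length")
  }
  tab <- table[, req]
  tab$ratio <- tab$unique_bp / tab$length
  tab$ratio_pct <- round_half_up(100 * tab$ratio, 2)
  list(table = tab,
       mean_ratio = mean(tab$ratio),
       mean_ratio_pct = round_half_up(100 * mean(tab$ratio), 2),
       r_length_count = if (nrow(tab) >= 2 && stats::var(tab$length) > 0 &&
                              stats::var(tab$n_cnvr) > 0) {
         pearson_r(tab$length, tab$n_cnvr)
       } else NA_real_)
}

#' Genome-wide unique coverage of a CNVR set
#'
#' @param cnvrs CNVR data.frame.
#' @param genome Genome metadata data.frame.
#' @return A list: `unique_bp` (union length over all chromosomes) and
#'   `fraction` (of the summed chromosome lengths).
#' @export
genome_coverage <- function(cnvrs, genome) {
  genome <- validate_genome(genome)
  ub <- if (nrow(cnvrs)) union_length(cnvrs) else 0
  list(unique_bp = ub, fraction = ub / sum(genome$length))
}

#' Size, frequency, and type statistics of a CNVR set
#'
#' @param cnvrs CNVR data.frame (at least one row).
#' @return A list: `n`, length summary (`min_len`, `max_len`, `mean_len`,
#'   `median_len`, in bp), `freq_spectrum` (named integer vector: CNVR
#'   count per carrier count), and `type_counts` (named vector over
#'   gain/loss/mixed summing to `n`).
#' @export
size_frequency_stats <- function(cnvrs) {
  if (nrow(cnvrs) == 0) stop_cnvreg("no CNVRs to summarise")
  len <- cnvrs$end - cnvrs$start
  spec <- table(factor(cnvrs$frequency, levels = seq_len(max(cnvrs$frequency))))
  tc <- vapply(c(gain = "gain", loss = "loss", mixed = "mixed"),
               function(t) sum(cnvrs$type == t), numeric(1))
  list(n = nrow(cnvrs),
       min_len = min(len), max_len = max(len),
       mean_len = mean(len), median_len = stats::median(len),
       freq_spectrum = stats::setNames(as.integer(spec), names(spec)),
       type_counts = tc)
}

#' Pearson product-moment correlation
#'
#' Validated wrapper around [stats::cor()]: requires equal lengths of at
#' least 2 and returns `NA` (with a warning) when either input has zero
#' variance.
#'
#' @param x,y Numeric vectors.
#' @return The correlation coefficient in `[-1, 1]`, or `NA`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    stop_cnvreg("need equal-length vectors of length >= 2")
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("zero variance: correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(x, y)
}
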