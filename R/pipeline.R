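#' Run the full CNVR discovery and characterization pipeline
#'
#' Orchestrates the stages in order: consensus filtering of primary-caller
#' calls by the support caller, within-sample merging, cross-sample CNVR
#' construction, minimum-length filtering, per-chromosome and
#' size/frequency summaries, trio concordance (when trios can be derived
#' from the pedigree), gene/QTL annotation overlap, breed-specificity, and
#' QTL trait enrichment. The returned report records the thresholds and
#' flags in force and the call/region counts at every stage, so a run is
#' auditable end to end.
#'
#' @param primary Call data.frame from the primary caller.
#' @param support Call data.frame from the support caller.
#' @param genome Genome metadata data.frame.
#' @param pedigree Pedigree data.frame.
#' @param genes,qtl,external Optional feature data.frames for annotation
#'   overlap, trait enrichment, and cross-study comparison.
#' @param thresholds A [cnv_thresholds()] object.
#' @param alpha Significance level for enrichment.
#' @param match_type Require type agreement in consensus filtering.
#' @param semantics Cross-sample merge semantics (see [build_cnvrs()]).
#' @return A list with `cnvrs`, `retained`, `chrom_summary`, `stats`,
#'   `trio` (or `NULL`), `gene_overlap`, `breed_specific`, `enrichment`,
#'   `external`, and `report` (stage counts, thresholds, flags).
#' @export
run_pipeline <- function(primary, support, genome, pedigree,
                         genes = NULL, qtl = NULL, external = NULL,
                         thresholds = cnv_thresholds(), alpha = 0.05,
                         match_type = FALSE,
                         semantics = c("component", "clique")) {
  semantics <- match.arg(semantics)
  genome <- validate_genome(genome)
  pedigree <- validate_pedigree(pedigree)
  validate_calls(primary, genome)
  validate_calls(support, genome)

  retained <- filter_supported_calls(primary, support, thresholds,
                                     match_type = match_type,
                                     samples = pedigree$sample)
  merged <- merge_within_samples(retained)
  cnvrs_raw <- build_cnvrs(merged, thresholds, semantics = semantics)
  cnvrs <- filter_min_length(cnvrs_raw, thresholds)

  chrom_sum <- chromosome_summary(cnvrs, genome)
  stats <- if (nrow(cnvrs)) size_frequency_stats(cnvrs) else NULL

  trios <- derive_trios(pedigree)
  trio <- if (nrow(trios) && nrow(cnvrs)) {
    trio_report(cnvrs, trios, samples = pedigree$sample)
  } else NULL

  gene_overlap <- if (!is.null(genes)) {
    overlap_features(cnvrs, genes, thresholds, genome)
  } else NULL
  breed <- if (nrow(cnvrs)) breed_specific(cnvrs, pedigree) else NULL
  enr <- if (!is.null(qtl) && nrow(cnvrs)) {
    qtl_enrichment(cnvrs, qtl, thresholds, alpha = alpha)
  } else NULL
  ext <- if (!is.null(external) && nrow(cnvrs)) {
    compare_external(cnvrs, external)
  } else NULL

  report <- list(
    thresholds = thresholds,
    flags = list(match_type = match_type, semantics = semantics,
                 alpha = alpha),
    counts = list(
      n_primary = nrow(primary), n_support = nrow(support),
      n_retained = nrow(retained), n_within_merged = nrow(merged),
      n_cnvr_raw = nrow(cnvrs_raw), n_cnvr = nrow(cnvrs)),
    type_counts = if (!is.null(stats)) stats$type_counts else NULL,
    genome_coverage = genome_coverage(cnvrs, genome))

  list(cnvrs = cnvrs, retained = retained, chrom_summary = chrom_sum,
       stats = stats, trio = trio, gene_overlap = gene_overlap,
       breed_specific = breed, enrichment = enr, external = ext,
       report = report)
}
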