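## Parent-offspring trio concordance: transmission and inheritance rates
## over CNVR carrier sets, and the derived call error rate.

#' Derive sequenced parent-offspring trios from a pedigree
#'
#' A trio is any sample whose sire and dam both appear in the sample
#' table.
#'
#' @param pedigree Pedigree data.frame (see [read_pedigree()]).
#' @return A data.frame with columns `child`, `sire`, `dam`.
#' @export
derive_trios <- function(pedigree) {
  ok <- !is.na(pedigree$sire) & !is.na(pedigree$dam) &
    pedigree$sire %in% pedigree$sample & pedigree$dam %in% pedigree$sample
  data.frame(child = pedigree$sample[ok], sire = pedigree$sire[ok],
             dam = pedigree$dam[ok], stringsAsFactors = FALSE)
}

carried_by <- function(cnvrs, sample) {
  vapply(cnvrs$carriers, function(cc) sample %in% cc, logical(1))
}

check_known_samples <- function(ids, samples) {
  if (is.null(samples)) return(invisible())
  unknown <- setdiff(ids, samples)
  if (length(unknown)) {
    stop_cnvreg("unknown sample id(s): ", paste(unknown, collapse = ", "))
  }
}

#' Transmission and inheritance rates over CNVR carrier sets
#'
#' `transmission_rate()` is the fraction of the parent's CNVRs also
#' carried by the child (the biological ideal is 0.5 for a heterozygous
#' variant; the metric's ceiling is 1). `inheritance_rate()` is the
#' fraction of the child's CNVRs carried by at least one parent; its
#' complement approximates the CNVR call error rate when de novo and
#' somatic events are rare. Both are undefined (`NA`) when the denominator
#' sample carries no CNVR.
#'
#' "Called in" a sample means the sample is a carrier of the
#' population-level CNVR, not a re-overlap of raw per-sample calls.
#'
#' @param cnvrs CNVR data.frame (see [build_cnvrs()]).
#' @param parent,child,sire,dam Sample ids.
#' @param samples Optional vector of known sample ids for validation.
#' @return A proportion in `[0, 1]`, or `NA` when undefined.
#' @examples
#' cn <- build_cnvrs(data.frame(
#'   chrom = "chr1", start = c(0, 0, 1000, 1000), end = c(500, 500, 1600, 1600),
#'   sample = c("p", "c", "p", "p2"), type = "loss", cn = 1, caller = "A"))
#' transmission_rate(cn, "p", "c")  # 1 of p's 2 CNVRs in c
#' @export
transmission_rate <- function(cnvrs, parent, child, samples = NULL) {
  check_known_samples(c(parent, child), samples)
  in_parent <- carried_by(cnvrs, parent)
  if (!any(in_parent)) return(NA_real_)
  sum(in_parent & carried_by(cnvrs, child)) / sum(in_parent)
}

#' @rdname transmission_rate
#' @export
inheritance_rate <- function(cnvrs, child, sire, dam, samples = NULL) {
  check_known_samples(c(child, sire, dam), samples)
  in_child <- carried_by(cnvrs, child)
  if (!any(in_child)) return(NA_real_)
  sum(in_child & (carried_by(cnvrs, sire) | carried_by(cnvrs, dam))) /
    sum(in_child)
}

#' Per-trio concordance report
#'
#' One row per trio with paternal transmission, maternal transmission and
#' inheritance rates, summarised by [summarize_trio_rates()]. Trios with an
#' undefined rate keep their row (with `NA`) but are excluded from the
#' corresponding mean, with a warning.
#'
#' @param cnvrs CNVR data.frame.
#' @param trios Trio data.frame (`child`, `sire`, `dam`), e.g. from
#'   [derive_trios()].
#' @param samples Optional known sample ids for validation.
#' @return A list with `rates` (per-trio data.frame) and the summary
#'   fields of [summarize_trio_rates()].
#' @export
trio_report <- function(cnvrs, trios, samples = NULL) {
  if (nrow(trios) == 0) stop_cnvreg("no trios to evaluate")
  rates <- data.frame(
    trio = seq_len(nrow(trios)), child = trios$child, sire = trios$sire,
    dam = trios$dam,
    paternal_transmission = mapply(function(s, c)
      transmission_rate(cnvrs, s, c, samples), trios$sire, trios$child),
    maternal_transmission = mapply(function(d, c)
      transmission_rate(cnvrs, d, c, samples), trios$dam, trios$child),
    inheritance = mapply(function(c, s, d)
      inheritance_rate(cnvrs, c, s, d, samples),
      trios$child, trios$sire, trios$dam),
    stringsAsFactors = FALSE)
  rownames(rates) <- NULL
  c(list(rates = rates), summarize_trio_rates(rates))
}

#' Summarise per-trio rates
#'
#' Unweighted column means (each trio counts once) and the derived error
#' rate, `1 - mean inheritance`. The error-rate reading assumes de novo
#' and somatic copy-number events are rare relative to calling error.
#'
#' @param rates Data.frame with columns `paternal_transmission`,
#'   `maternal_transmission`, `inheritance` (proportions; `NA` allowed).
#' @return A list: `mean_paternal`, `mean_maternal`, `mean_inheritance`,
#'   `error_rate`, `n_trios`.
#' @export
summarize_trio_rates <- function(rates) {
  req <- c("paternal_transmission", "maternal_transmission", "inheritance")
  if (!all(req %in% names(rates))) {
    stop_cnvreg("rates table must have columns: ", paste(req, collapse = ", "))
  }
  if (anyNA(rates[req])) {
    warning("trio(s) with undefined rate excluded from means", call. = FALSE)
  }
  mi <- mean(rates$inheritance, na.rm = TRUE)
  list(mean_paternal = mean(rates$paternal_transmission, na.rm = TRUE),
       mean_maternal = mean(rates$maternal_transmission, na.rm = TRUE),
       mean_inheritance = mi,
       error_rate = 1 - mi,
       n_trios = nrow(rates))
}
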