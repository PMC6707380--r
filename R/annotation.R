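## CNVR annotation: overlap with gene/QTL tracks, breed-specificity, and
## cross-study comparison.

#' Overlap CNVRs with an annotation track
#'
#' Reports every (CNVR, feature) pair sharing at least
#' `min_feature_overlap` bp (default a single base). Overlap is evaluated
#' against the CNVR union span, not member calls.
#'
#' @param cnvrs CNVR data.frame.
#' @param features Feature data.frame (see [read_features()]).
#' @param thresholds A [cnv_thresholds()].
#' @param genome Optional genome metadata; feature chromosomes absent from
#'   it raise an error.
#' @return A data.frame with one row per overlapping pair: `cnvr_id`,
#'   `feature_id`, `class`, `label`, `overlap_bp`.
#' @seealso [overlap_rollup()] for distinct-count summaries.
#' @export
overlap_features <- function(cnvrs, features, thresholds = cnv_thresholds(),
                             genome = NULL) {
  if (!is.null(genome)) {
    unknown <- setdiff(unique(features$chrom), genome$chrom)
    if (length(unknown)) {
      stop_cnvreg("feature chromosome(s) absent from genome metadata: ",
                  paste(unknown, collapse = ", "))
    }
  }
  if (nrow(cnvrs) == 0 || nrow(features) == 0) {
    return(data.frame(cnvr_id = character(), feature_id = character(),
                      class = character(), label = character(),
                      overlap_bp = numeric(), stringsAsFactors = FALSE))
  }
  fidx <- split(seq_len(nrow(features)), features$chrom)
  rows <- lapply(seq_len(nrow(cnvrs)), function(i) {
    fi <- fidx[[cnvrs$chrom[i]]]
    if (is.null(fi)) return(NULL)
    ov <- ov_bp(cnvrs$start[i], cnvrs$end[i],
                features$start[fi], features$end[fi])
    hit <- fi[ov >= thresholds$min_feature_overlap]
    if (!length(hit)) return(NULL)
    data.frame(cnvr_id = cnvrs$cnvr_id[i], feature_id = features$feature_id[hit],
               class = features$class[hit], label = features$label[hit],
               overlap_bp = ov[ov >= thresholds$min_feature_overlap],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(cnvr_id = character(),
                                      feature_id = character(),
                                      class = character(), label = character(),
                                      overlap_bp = numeric(),
                                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @rdname overlap_features
#' @param pairs Output of `overlap_features()`.
#' @export
overlap_rollup <- function(pairs) {
  list(n_cnvrs_overlapped = length(unique(pairs$cnvr_id)),
       n_features_overlapped = length(unique(pairs$feature_id)),
       n_pairs = nrow(pairs),
       features_per_class = if (nrow(pairs)) {
         tab <- table(pairs$class[!duplicated(pairs$feature_id)])
         stats::setNames(as.integer(tab), names(tab))
       } else integer(0))
}

#' Breed-specific CNVRs
#'
#' A CNVR is breed-specific when all of its carriers belong to a single
#' breed. Every carrier must have a breed label in the pedigree.
#'
#' @param cnvrs CNVR data.frame.
#' @param pedigree Pedigree data.frame with `sample` and `breed`.
#' @return The breed-specific subset of `cnvrs` with added columns
#'   `breed` and `single_carrier`; the proportion of single-carrier rows
#'   is attached as attribute `"prop_single_carrier"`.
#' @export
breed_specific <- function(cnvrs, pedigree) {
  breed <- stats::setNames(pedigree$breed, pedigree$sample)
  carriers <- unique(unlist(cnvrs$carriers))
  nolab <- carriers[!carriers %in% names(breed) | is.na(breed[carriers])]
  if (length(nolab)) {
    stop_cnvreg("carrier(s) without breed label: ",
                paste(nolab, collapse = ", "))
  }
  cb <- lapply(cnvrs$carriers, function(cc) unique(unname(breed[cc])))
  keep <- lengths(cb) == 1
  out <- cnvrs[keep, , drop = FALSE]
  out$breed <- unlist(cb[keep])
  out$single_carrier <- lengths(cnvrs$carriers[keep]) == 1
  attr(out, "prop_single_carrier") <-
    if (nrow(out)) mean(out$single_carrier) else NA_real_
  out
}

#' Compare CNVRs with an external study's regions
#'
#' Cross-study concordance uses the loosest criterion: two regions are
#' considered overlapped when they share at least one base. Reports how
#' many of *this* study's CNVRs are hit by at least one external region,
#' and that count as a percentage of the total (half-up rounding to two
#' decimals, as such tables are conventionally printed).
#'
#' @param cnvrs CNVR data.frame.
#' @param external Interval data.frame of the external study's regions.
#' @return A list: `n_overlapped`, `n_total`, `ratio_pct` (rounded),
#'   `ratio` (raw proportion).
#' @export
compare_external <- function(cnvrs, external) {
  if (nrow(external) == 0) stop_cnvreg("external CNVR set is empty")
  validate_intervals(external, what = "external region")
  eidx <- split(seq_len(nrow(external)), external$chrom)
  hit <- vapply(seq_len(nrow(cnvrs)), function(i) {
    ei <- eidx[[cnvrs$chrom[i]]]
    if (is.null(ei)) return(FALSE)
    any(ov_bp(cnvrs$start[i], cnvrs$end[i],
              external$start[ei], external$end[ei]) >= 1)
  }, logical(1))
  n <- sum(hit)
  list(n_overlapped = n, n_total = nrow(cnvrs),
       ratio_pct = round_half_up(100 * n / nrow(cnvrs), 2),
       ratio = n / nrow(cnvrs))
}
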