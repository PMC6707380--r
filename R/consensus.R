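#' Consensus filtering of primary-caller calls by a second caller
#'
#' Retains a primary call when at least one *single* support call from the
#' same sample covers at least `support_frac` of the primary call's length
#' (one-way overlap fraction, measured against the primary call). This is
#' the standard false-positive control for pairing a per-sample
#' breakpoint-sensitive caller with an orthogonal multi-sample read-depth
#' caller: a primary call with no read-depth corroboration is dropped.
#'
#' The threshold is inclusive (fraction `>= support_frac`). Support is
#' evaluated per single support call, not against the union of support
#' coverage, and must come from the same sample. Call type (loss/gain) is
#' not required to agree unless `match_type = TRUE`.
#'
#' @param primary Call data.frame from the primary caller.
#' @param support Call data.frame from the supporting caller.
#' @param thresholds A [cnv_thresholds()] object; `support_frac` is used.
#' @param match_type Require the support call's type to equal the primary
#'   call's type (default `FALSE`).
#' @param samples Optional character vector of known sample ids; support
#'   calls from samples outside it are dropped with a warning.
#' @return The retained subset of `primary`, unmodified, ordered by
#'   (chrom, start, end, sample).
#' @examples
#' thr <- cnv_thresholds()
#' p <- data.frame(chrom = "chr1", start = 1000, end = 2000,
#'                 sample = "s1", type = "loss", cn = 1, caller = "A")
#' s <- data.frame(chrom = "chr1", start = 1900, end = 3000,
#'                 sample = "s1", type = "loss", cn = 1, caller = "B")
#' filter_supported_calls(p, s, thr)  # retained: fraction exactly 0.10
#' @export
filter_supported_calls <- function(primary, support, thresholds = cnv_thresholds(),
                                   match_type = FALSE, samples = NULL) {
  validate_calls(primary)
  if (nrow(support)) validate_calls(support)
  if (!is.null(samples)) {
    unknown <- setdiff(unique(support$sample), samples)
    if (length(unknown)) {
      warning("support calls from unknown sample(s) ignored: ",
              paste(unknown, collapse = ", "), call. = FALSE)
      support <- support[support$sample %in% samples, , drop = FALSE]
    }
  }
  if (nrow(support) == 0) {
    warning("empty support call set: no primary calls retained", call. = FALSE)
    return(primary[0, , drop = FALSE])
  }
  pkey <- paste(primary$sample, primary$chrom)
  skey <- paste(support$sample, support$chrom)
  sidx <- split(seq_len(nrow(support)), skey)
  keep <- logical(nrow(primary))
  for (g in split(seq_len(nrow(primary)), pkey)) {
    si <- sidx[[paste(primary$sample[g[1]], primary$chrom[g[1]])]]
    if (is.null(si)) next
    ss <- support$start[si]; se <- support$end[si]; st <- support$type[si]
    for (i in g) {
      ok <- ov_bp(primary$start[i], primary$end[i], ss, se) /
        (primary$end[i] - primary$start[i]) >= thresholds$support_frac
      if (match_type) ok <- ok & st == primary$type[i]
      keep[i] <- any(ok)
    }
  }
  out <- primary[keep, , drop = FALSE]
  out[order_intervals(out, "sample"), , drop = FALSE]
}
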