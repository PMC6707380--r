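#' @keywords internal
"_PACKAGE"

# Round half away from zero, matching how the field's tables print
# percentages (base round() is half-to-even).
round_half_up <- function(x, digits = 2) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

# Natural chromosome sort key: numeric bodies first in numeric order, then
# X, Y, then anything else. Prefixes such as "chr"/"SSC" are ignored.
chrom_key <- function(chrom) {
  body <- sub("^(chr|Chr|CHR|SSC|ssc)", "", chrom)
  num <- suppressWarnings(as.numeric(body))
  ifelse(!is.na(num), num,
    ifelse(toupper(body) == "X", 1e6,
      ifelse(toupper(body) == "Y", 1e6 + 1, 2e6)))
}

# Deterministic (chrom, start, end, ...) ordering used for all outputs.
order_intervals <- function(df, extra = character()) {
  cols <- list(chrom_key(df$chrom), df$chrom, df$start, df$end)
  for (e in extra) cols <- c(cols, list(df[[e]]))
  do.call(order, cols)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cnvreg <- function(...) stop(..., call. = FALSE)

#' Path to a bundled reference data file
#'
#' Convenience accessor for the plain-text reference tables shipped with the
#' package (published summary values from a 240-animal swine whole-genome
#' CNV survey, used by the examples, tests and acceptance script).
#'
#' @param file File name under `extdata/`; with no argument, lists the
#'   available files.
#' @return A file path (or a character vector of file names).
#' @export
cnvreg_extdata <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "cnvreg")))
  }
  path <- system.file("extdata", file, package = "cnvreg")
  if (!nzchar(path)) stop_cnvreg("no bundled file named '", file, "'")
  path
}
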