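## File readers and writers.
##
## TSV inputs (calls, pedigree, genome metadata) are headered; BED inputs
## (features, external CNVR sets) are headerless. BED and all internal
## coordinates are 0-based half-open; GFF3 (1-based inclusive) is converted
## on read. Missing values are written as ".".

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop_cnvreg(what, " file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = ".",
                          comment.char = "", quote = "")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_cnvreg(what, " file ", path, " lacks column(s): ",
                paste(missing, collapse = ", "))
  }
  df
}

#' Read genome metadata
#'
#' Headered TSV with columns `chrom`, `length`, `category`
#' (`autosome`/`X`/`Y`). The category drives expected ploidy: autosomes are
#' diploid in both sexes, X is diploid in females and haploid in males, Y is
#' absent in females and haploid in males.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with columns `chrom`, `length`, `category`.
#' @seealso [expected_ploidy()]
#' @export
read_genome <- function(path) {
  g <- read_tsv_checked(path, c("chrom", "length", "category"), "genome")
  validate_genome(g)
}

validate_genome <- function(g) {
  if (anyDuplicated(g$chrom)) stop_cnvreg("duplicated chromosome names")
  if (any(!is.finite(g$length) | g$length <= 0)) {
    stop_cnvreg("chromosome lengths must be positive")
  }
  bad <- setdiff(unique(g$category), c("autosome", "X", "Y"))
  if (length(bad)) {
    stop_cnvreg("unknown chromosome category: ", paste(bad, collapse = ", "))
  }
  g[order(chrom_key(g$chrom), g$chrom), , drop = FALSE]
}

#' Expected copy number of a chromosome by sex
#'
#' @param category Chromosome category (`autosome`, `X`, or `Y`).
#' @param sex `male` or `female` (recycled against `category`).
#' @return Integer expected ploidy (0, 1, or 2).
#' @examples
#' expected_ploidy("X", c("male", "female"))  # 1 2
#' @export
expected_ploidy <- function(category, sex) {
  n <- max(length(category), length(sex))
  category <- rep_len(category, n); sex <- rep_len(sex, n)
  out <- integer(n)
  out[category == "autosome"] <- 2L
  out[category == "X"] <- ifelse(sex[category == "X"] == "male", 1L, 2L)
  out[category == "Y"] <- ifelse(sex[category == "Y"] == "male", 1L, 0L)
  out
}

#' Read and write per-sample CNV call tables
#'
#' Headered TSV with columns `chrom`, `start`, `end`, `sample`, `type`
#' (`loss`/`gain`), `cn` (copy-number estimate, `.` when absent) and
#' `caller`. Coordinates are validated (and, when `genome` is given,
#' checked against chromosome bounds) with the offending line reported.
#'
#' @param path File path.
#' @param genome Optional genome metadata for bounds checking.
#' @param calls A call data.frame to write.
#' @return `read_calls()`: a call data.frame sorted by (chrom, start, end,
#'   sample); `write_calls()`: the path, invisibly.
#' @export
read_calls <- function(path, genome = NULL) {
  df <- read_tsv_checked(
    path, c("chrom", "start", "end", "sample", "type", "cn", "caller"),
    "call")
  df$cn <- suppressWarnings(as.numeric(df$cn))
  validate_calls(df, genome, file = path)
  df[order_intervals(df, "sample"), , drop = FALSE]
}

validate_calls <- function(df, genome = NULL, file = NULL) {
  where <- function(rows) {
    if (is.null(file)) paste("row", paste(utils::head(rows, 5), collapse = ", "))
    else paste0(file, " line ", paste(utils::head(rows + 1, 5), collapse = ", "))
  }
  bad <- which(!is.finite(df$start) | !is.finite(df$end) |
                 df$start < 0 | df$start >= df$end)
  if (length(bad)) {
    stop_cnvreg("call with end <= start (or negative start) at ", where(bad))
  }
  badt <- which(!df$type %in% c("loss", "gain"))
  if (length(badt)) {
    stop_cnvreg("call type must be 'loss' or 'gain' at ", where(badt))
  }
  if (!is.null(genome)) validate_intervals(df, genome, what = "call")
  invisible(df)
}

#' @rdname read_calls
#' @export
write_calls <- function(calls, path) {
  out <- calls[, c("chrom", "start", "end", "sample", "type", "cn", "caller")]
  out$cn <- ifelse(is.na(out$cn), ".", format(out$cn, trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pedigree / sample table
#'
#' Headered TSV with columns `sample`, `sire`, `dam`, `sex`
#' (`male`/`female`), `breed`, `coverage` (mean sequence depth, `.` when
#' unknown). Unknown parents are `.`. Checks sample uniqueness, parental
#' sex consistency, and that no sample is its own ancestor.
#'
#' @param path File path.
#' @return A pedigree data.frame.
#' @export
read_pedigree <- function(path) {
  ped <- read_tsv_checked(
    path, c("sample", "sire", "dam", "sex", "breed", "coverage"), "pedigree")
  ped$coverage <- suppressWarnings(as.numeric(ped$coverage))
  validate_pedigree(ped)
}

validate_pedigree <- function(ped) {
  if (anyDuplicated(ped$sample)) {
    stop_cnvreg("duplicated sample id(s) in pedigree: ",
                paste(unique(ped$sample[duplicated(ped$sample)]), collapse = ", "))
  }
  if (any(!ped$sex %in% c("male", "female"))) {
    stop_cnvreg("sex must be 'male' or 'female'")
  }
  sex <- stats::setNames(ped$sex, ped$sample)
  sires <- stats::na.omit(unique(ped$sire))
  bad <- sires[sires %in% names(sex) & sex[sires] != "male"]
  if (length(bad)) stop_cnvreg("sire(s) not male: ", paste(bad, collapse = ", "))
  dams <- stats::na.omit(unique(ped$dam))
  bad <- dams[dams %in% names(sex) & sex[dams] != "female"]
  if (length(bad)) stop_cnvreg("dam(s) not female: ", paste(bad, collapse = ", "))
  # ancestry cycle check by iterative parent lookup
  for (s in ped$sample) {
    frontier <- s; seen <- character()
    repeat {
      idx <- stats::na.omit(match(frontier, ped$sample))
      parents <- setdiff(unique(stats::na.omit(c(ped$sire[idx], ped$dam[idx]))), seen)
      if (!length(parents)) break
      if (s %in% parents) stop_cnvreg("sample ", s, " is its own ancestor")
      seen <- union(seen, parents)
      frontier <- parents
    }
  }
  ped
}

#' @rdname read_pedigree
#' @param pedigree A pedigree data.frame to write.
#' @export
write_pedigree <- function(pedigree, path) {
  out <- pedigree[, c("sample", "sire", "dam", "sex", "breed", "coverage")]
  for (col in c("sire", "dam", "coverage")) {
    out[[col]] <- ifelse(is.na(out[[col]]), ".", as.character(out[[col]]))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an annotation track (genes, QTL, or external CNVR sets)
#'
#' BED input is headerless with columns `chrom start end id class label`
#' (extra columns ignored; missing `class`/`label` filled with `"."`),
#' 0-based half-open. GFF3 input is parsed with `rtracklayer` and
#' converted from 1-based inclusive coordinates; only record types present
#' in `gff3_class_map` are kept, and each is mapped to a feature class
#' (defaults cover the usual gene biotypes).
#'
#' @param path File path.
#' @param format `"bed"` or `"gff3"`; default guesses from the extension.
#' @param gff3_class_map Named character vector mapping GFF3 `type` values
#'   to feature classes.
#' @param label Optional single label applied to every record (e.g. a study
#'   name for an external CNVR set).
#' @return A feature data.frame with columns `chrom`, `start`, `end`,
#'   `feature_id`, `class`, `label`.
#' @export
read_features <- function(path, format = c("auto", "bed", "gff3"),
                          gff3_class_map = c(
                            gene = "gene", pseudogene = "pseudogene",
                            lnc_RNA = "ncRNA", ncRNA = "ncRNA",
                            snoRNA = "ncRNA", snRNA = "ncRNA",
                            rRNA = "ncRNA", tRNA = "ncRNA",
                            miRNA = "miscRNA", transcript = "miscRNA"),
                          label = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) "gff3" else "bed"
  }
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    keep <- as.character(gr$type) %in% names(gff3_class_map)
    gr <- gr[keep]
    ids <- gr$ID
    if (is.null(ids)) ids <- paste0("feat", seq_along(gr))
    ids[is.na(ids)] <- paste0("feat", which(is.na(ids)))
    df <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
      end = GenomicRanges::end(gr),
      feature_id = as.character(ids),
      class = unname(gff3_class_map[as.character(gr$type)]),
      label = if (!is.null(gr$biotype)) as.character(gr$biotype) else ".",
      stringsAsFactors = FALSE)
  } else {
    raw <- utils::read.table(path, header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE, comment.char = "#",
                             quote = "")
    if (ncol(raw) < 3) stop_cnvreg("BED file ", path, " needs >= 3 columns")
    df <- data.frame(
      chrom = as.character(raw[[1]]), start = raw[[2]], end = raw[[3]],
      feature_id = if (ncol(raw) >= 4) as.character(raw[[4]])
                   else paste0("feat", seq_len(nrow(raw))),
      class = if (ncol(raw) >= 5) as.character(raw[[5]]) else ".",
      label = if (ncol(raw) >= 6) as.character(raw[[6]]) else ".",
      stringsAsFactors = FALSE)
  }
  if (!is.null(label)) df$label <- label
  if (anyDuplicated(df$feature_id)) {
    df$feature_id <- make.unique(df$feature_id, sep = "_")
  }
  validate_intervals(df, what = "feature")
  df[order_intervals(df), , drop = FALSE]
}

#' @rdname read_features
#' @param features A feature data.frame to write (as BED).
#' @export
write_features <- function(features, path) {
  utils::write.table(
    features[, c("chrom", "start", "end", "feature_id", "class", "label")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write CNVR tables as BED6+
#'
#' Columns: `chrom start end cnvr_id frequency strand(".") type n_members
#' carriers` with carriers comma-separated. Round-trips the CNVR tables
#' produced by [build_cnvrs()] (member call indices are not preserved).
#'
#' @param cnvrs A CNVR data.frame.
#' @param path File path.
#' @return `read_cnvr_bed()`: a CNVR data.frame; `write_cnvr_bed()`: the
#'   path, invisibly.
#' @export
write_cnvr_bed <- function(cnvrs, path) {
  out <- data.frame(
    chrom = cnvrs$chrom, start = cnvrs$start, end = cnvrs$end,
    cnvr_id = cnvrs$cnvr_id, frequency = cnvrs$frequency, strand = ".",
    type = cnvrs$type, n_members = cnvrs$n_members,
    carriers = vapply(cnvrs$carriers, paste, "", collapse = ","),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_cnvr_bed
#' @export
read_cnvr_bed <- function(path) {
  raw <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "")
  if (ncol(raw) < 9) stop_cnvreg("CNVR BED ", path, " needs 9 columns")
  df <- data.frame(
    chrom = as.character(raw[[1]]), start = raw[[2]], end = raw[[3]],
    cnvr_id = as.character(raw[[4]]), type = as.character(raw[[7]]),
    frequency = as.integer(raw[[5]]), n_members = as.integer(raw[[8]]),
    stringsAsFactors = FALSE)
  df$carriers <- strsplit(as.character(raw[[9]]), ",", fixed = TRUE)
  validate_intervals(df, what = "CNVR")
  df
}
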