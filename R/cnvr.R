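## CNVR construction: within-sample merging of calls, cross-sample merging
## under the reciprocal-overlap criterion, typing, and length filtering.

#' Merge one sample's overlapping same-type calls
#'
#' Within a single genome, calls of the same type that share at least 1 bp
#' are replaced by their union interval (touching intervals do not merge
#' under half-open arithmetic). The merged call's copy number is the
#' length-weighted mean of its members' estimates when all are present,
#' `NA` otherwise; caller labels are concatenated.
#'
#' @param calls Call data.frame, all rows from the same sample.
#' @return A call data.frame with merged rows, ordered by (chrom, start).
#' @examples
#' x <- data.frame(chrom = "chr1", start = c(0, 50), end = c(100, 150),
#'                 sample = "s1", type = "loss", cn = c(1, 1), caller = "A")
#' merge_within_sample(x)  # one loss call [0, 150)
#' @export
merge_within_sample <- function(calls) {
  validate_calls(calls)
  if (length(unique(calls$sample)) > 1) {
    stop_cnvreg("merge_within_sample() expects calls from a single sample")
  }
  if (nrow(calls) <= 1) return(calls)
  pieces <- lapply(split(calls, paste(calls$chrom, calls$type)), function(d) {
    d <- d[order(d$start, d$end), , drop = FALSE]
    grp <- integer(nrow(d)); g <- 1L; grp[1] <- g; cur_end <- d$end[1]
    for (i in seq_len(nrow(d))[-1]) {
      if (d$start[i] < cur_end) {        # >= 1 bp overlap (strict half-open)
        grp[i] <- g
        cur_end <- max(cur_end, d$end[i])
      } else {
        g <- g + 1L; grp[i] <- g; cur_end <- d$end[i]
      }
    }
    do.call(rbind, lapply(split(d, grp), function(m) {
      data.frame(
        chrom = m$chrom[1], start = min(m$start), end = max(m$end),
        sample = m$sample[1], type = m$type[1],
        cn = if (anyNA(m$cn)) NA_real_ else
          sum(m$cn * (m$end - m$start)) / sum(m$end - m$start),
        caller = paste(unique(m$caller), collapse = ","),
        stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order_intervals(out), , drop = FALSE]
}

#' @rdname merge_within_sample
#' @param calls_all Call data.frame covering any number of samples; each
#'   sample is merged independently.
#' @export
merge_within_samples <- function(calls_all) {
  if (nrow(calls_all) <= 1) return(calls_all)
  out <- do.call(rbind, lapply(split(calls_all, calls_all$sample),
                               merge_within_sample))
  rownames(out) <- NULL
  out[order_intervals(out, "sample"), , drop = FALSE]
}

# Union-find with path halving; used for component merging.
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Merge calls across samples into CNVRs
#'
#' Calls (typically already merged within each sample) are grouped into
#' copy number variable regions. Under the default `"component"` semantics
#' a CNVR is a connected component of the graph joining every pair of
#' calls with reciprocal overlap at or above `reciprocal_frac`; the region
#' grows transitively, so a pair `[a, b)` / `[c, d)` with `a < c < b < d`
#' and sufficient reciprocal overlap yields a CNVR spanning `[a, d)`.
#' `"clique"` semantics instead require every pair inside a CNVR to
#' satisfy the criterion (calls are assigned greedily in coordinate
#' order), for sensitivity analysis.
#'
#' CNVR type is `gain` when all member calls are gains, `loss` when all
#' are losses, `mixed` otherwise; merging itself ignores type. Ids are
#' `CNVR0001`, ... in (chrom, start) order.
#'
#' @param calls Call data.frame.
#' @param thresholds A [cnv_thresholds()]; `reciprocal_frac` is used.
#' @param semantics `"component"` (default) or `"clique"`.
#' @return A CNVR data.frame with columns `chrom`, `start`, `end`,
#'   `cnvr_id`, `type`, `frequency`, `n_members`, and list-columns
#'   `carriers` (sorted sample ids) and `member_idx` (row indices into
#'   `calls`).
#' @examples
#' calls <- data.frame(chrom = "chr1", start = c(0, 40), end = c(100, 140),
#'                     sample = c("s1", "s2"), type = "loss", cn = 1,
#'                     caller = "A")
#' build_cnvrs(calls)  # one CNVR spanning [0, 140)
#' @export
build_cnvrs <- function(calls, thresholds = cnv_thresholds(),
                        semantics = c("component", "clique")) {
  semantics <- match.arg(semantics)
  if (nrow(calls) == 0) return(empty_cnvrs())
  validate_calls(calls)
  ord <- order_intervals(calls, "sample")
  comp <- integer(nrow(calls))          # component id per original row
  next_comp <- 0L
  for (rows in split(ord, calls$chrom[ord])) {
    s <- calls$start[rows]; e <- calls$end[rows]
    n <- length(rows)
    if (semantics == "component") {
      parent <- uf_new(n)
      active <- integer(0)              # indices with a live end, sorted by start
      for (i in seq_len(n)) {
        active <- active[e[active] > s[i]]
        for (j in active) {
          ov <- ov_bp(s[i], e[i], s[j], e[j])
          if (min(ov / (e[i] - s[i]), ov / (e[j] - s[j])) >=
                thresholds$reciprocal_frac) {
            ri <- uf_find(parent, i); rj <- uf_find(parent, j)
            if (ri != rj) parent[rj] <- ri
          }
        }
        active <- c(active, i)
      }
      roots <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
      comp[rows] <- next_comp + match(roots, unique(roots))
      next_comp <- next_comp + length(unique(roots))
    } else {
      groups <- list()                  # each: vector of member indices
      for (i in seq_len(n)) {
        placed <- FALSE
        for (k in seq_along(groups)) {
          m <- groups[[k]]
          ov <- ov_bp(s[i], e[i], s[m], e[m])
          if (all(pmin(ov / (e[i] - s[i]), ov / (e[m] - s[m])) >=
                    thresholds$reciprocal_frac)) {
            groups[[k]] <- c(m, i); placed <- TRUE; break
          }
        }
        if (!placed) groups[[length(groups) + 1L]] <- i
      }
      for (k in seq_along(groups)) comp[rows[groups[[k]]]] <- next_comp + k
      next_comp <- next_comp + length(groups)
    }
  }
  rows_by_comp <- split(seq_len(nrow(calls)), comp)
  out <- do.call(rbind, lapply(rows_by_comp, function(m) {
    data.frame(chrom = calls$chrom[m[1]], start = min(calls$start[m]),
               end = max(calls$end[m]),
               type = assign_type(calls$type[m]),
               frequency = length(unique(calls$sample[m])),
               n_members = length(m), stringsAsFactors = FALSE)
  }))
  out$carriers <- lapply(rows_by_comp,
                         function(m) sort(unique(calls$sample[m])))
  out$member_idx <- lapply(rows_by_comp, function(m) sort(m))
  ord2 <- order_intervals(out)
  out <- out[ord2, , drop = FALSE]
  out$cnvr_id <- sprintf(paste0("CNVR%0", max(4, nchar(nrow(out))), "d"),
                         seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("chrom", "start", "end", "cnvr_id", "type", "frequency",
          "n_members", "carriers", "member_idx")]
}

empty_cnvrs <- function() {
  out <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                    cnvr_id = character(), type = character(),
                    frequency = integer(), n_members = integer(),
                    stringsAsFactors = FALSE)
  out$carriers <- list(); out$member_idx <- list()
  out
}

#' CNVR type from member call types
#'
#' `gain` if every member is a gain, `loss` if every member is a loss,
#' `mixed` when both occur among carriers.
#'
#' @param types Character vector of member call types (`loss`/`gain`).
#' @return `"gain"`, `"loss"`, or `"mixed"`.
#' @examples
#' assign_type(c("loss", "gain"))  # "mixed"
#' @export
assign_type <- function(types) {
  if (length(types) == 0) stop_cnvreg("CNVR must have at least one member")
  u <- unique(types)
  if (length(u) == 1) u else "mixed"
}

#' Drop CNVRs below the minimum length
#'
#' Removes regions strictly shorter than `min_cnvr_len` (default 200 bp; a
#' region of exactly the minimum length is kept). Survivors are untouched.
#'
#' @param cnvrs CNVR data.frame.
#' @param thresholds A [cnv_thresholds()].
#' @return The filtered CNVR data.frame.
#' @export
filter_min_length <- function(cnvrs, thresholds = cnv_thresholds()) {
  cnvrs[cnvrs$end - cnvrs$start >= thresholds$min_cnvr_len, , drop = FALSE]
}

#' CNVR-by-sample presence matrix
#'
#' Binary matrix with one row per CNVR and one column per sample; row sums
#' equal CNVR frequencies and column sums give per-sample CNVR counts.
#'
#' @param cnvrs CNVR data.frame.
#' @param samples Character vector of all sample ids (must cover every
#'   carrier).
#' @return An integer matrix (CNVR ids as rownames, sample ids as
#'   colnames).
#' @export
cnvr_presence <- function(cnvrs, samples) {
  unknown <- setdiff(unique(unlist(cnvrs$carriers)), samples)
  if (length(unknown)) {
    stop_cnvreg("carrier sample(s) absent from sample list: ",
                paste(unknown, collapse = ", "))
  }
  m <- matrix(0L, nrow = nrow(cnvrs), ncol = length(samples),
              dimnames = list(cnvrs$cnvr_id, samples))
  for (i in seq_len(nrow(cnvrs))) m[i, cnvrs$carriers[[i]]] <- 1L
  m
}
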