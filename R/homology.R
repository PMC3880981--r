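#' Parse tabular BLAST output (outfmt 6)
#'
#' Reads the standard 12-column tab-separated BLAST format (query, subject,
#' percent identity, alignment length, mismatches, gap opens, query
#' start/end, subject start/end, e-value, bit score). Self-hits are kept;
#' [best_hits()] filters them.
#'
#' @param path file path; an empty file yields a zero-row table.
#' @return data.frame with columns `query`, `subject`, `pct_identity`,
#'   `evalue`, `bitscore`.
#' @export
parse_blast_tabular <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(data.frame(query = character(0), subject = character(0),
                      pct_identity = numeric(0), evalue = numeric(0),
                      bitscore = numeric(0), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12)) {
    stop("BLAST tabular parse error at row ", which(nf != 12)[1],
         ": expected 12 tab-separated columns, got ", nf[which(nf != 12)[1]])
  }
  m <- do.call(rbind, fields)
  data.frame(query = m[, 1], subject = m[, 2],
             pct_identity = as.numeric(m[, 3]),
             evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12]),
             stringsAsFactors = FALSE)
}

#' Best hit per query at an e-value cutoff
#'
#' Hits with e-value above the cutoff and self-hits (query == subject) are
#' discarded; multiple HSPs for one query-subject pair are collapsed to the
#' minimum e-value (then highest bit score). The best hit per query is the
#' lowest e-value, ties broken by highest bit score, then lexicographically
#' smallest subject id, so the result is deterministic.
#'
#' @param hits data.frame from [parse_blast_tabular()].
#' @param cutoff e-value cutoff (hits must be `<=` cutoff); the
#'   reconstruction workflow uses 1e-30 for reaction transfer and a relaxed
#'   1e-10 pass for completing GPRs.
#' @return named character vector: `best["query"] = subject`, plus
#'   attribute `evalue` with the matching best e-values.
#' @export
best_hits <- function(hits, cutoff = 1e-30) {
  hits <- hits[hits$evalue <= cutoff & hits$query != hits$subject, , drop = FALSE]
  if (nrow(hits) == 0) {
    return(structure(character(0), evalue = numeric(0)))
  }
  # collapse HSPs: best row per (query, subject)
  ord <- order(hits$query, hits$subject, hits$evalue, -hits$bitscore)
  hits <- hits[ord, , drop = FALSE]
  hits <- hits[!duplicated(hits[c("query", "subject")]), , drop = FALSE]
  # best subject per query
  ord <- order(hits$query, hits$evalue, -hits$bitscore, hits$subject)
  hits <- hits[ord, , drop = FALSE]
  hits <- hits[!duplicated(hits$query), , drop = FALSE]
  structure(stats::setNames(hits$subject, hits$query),
            evalue = stats::setNames(hits$evalue, hits$query))
}

#' Bidirectional (mutual) best hits
#'
#' A reference gene r and target gene t are orthologs when r's best hit is
#' t and t's best hit is r, both directions passing the cutoff already
#' applied in [best_hits()]. The result is an injective partial matching:
#' no gene appears in two pairs.
#'
#' @param fwd best-hit map reference -> target (from [best_hits()]).
#' @param rev best-hit map target -> reference.
#' @return an `ortholog_map`: data.frame with columns `ref`, `target`,
#'   `evalue` (worst of the two directions, when available).
#' @export
bidirectional_best_hits <- function(fwd, rev) {
  refs <- if (is.null(names(fwd))) character(0) else names(fwd)
  keep <- vapply(refs, function(r) {
    t <- fwd[[r]]
    t %in% names(rev) && identical(rev[[t]], r)
  }, logical(1))
  refs <- refs[keep]
  targets <- unname(fwd[refs])
  ev_f <- attr(fwd, "evalue"); ev_r <- attr(rev, "evalue")
  ev <- rep(NA_real_, length(refs))
  if (!is.null(ev_f) && !is.null(ev_r)) {
    ev <- pmax(unname(ev_f[refs]), unname(ev_r[targets]))
  }
  structure(data.frame(ref = refs, target = targets, evalue = ev,
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("ortholog_map", "data.frame"))
}

#' Compute an ortholog map from two BLAST tables in one call
#'
#' @param fwd_hits,rev_hits data.frames from [parse_blast_tabular()]
#'   (reference-vs-target and target-vs-reference searches).
#' @param cutoff e-value cutoff applied to both directions.
#' @return an `ortholog_map` (see [bidirectional_best_hits()]).
#' @export
ortholog_map <- function(fwd_hits, rev_hits, cutoff = 1e-30) {
  bidirectional_best_hits(best_hits(fwd_hits, cutoff),
                          best_hits(rev_hits, cutoff))
}

#' @export
print.ortholog_map <- function(x, ...) {
  cat("<ortholog_map> ", nrow(x), " mutual best-hit pairs\n", sep = "")
  if (nrow(x)) print.data.frame(utils::head(x, 10))
  invisible(x)
}

#' Ortholog map as a named lookup vector
#' @param map an `ortholog_map`.
#' @return named character vector `reference gene -> target gene`.
#' @export
map_as_vector <- function(map) stats::setNames(map$target, map$ref)
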