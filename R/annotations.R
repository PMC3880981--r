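#' Collect gene-to-EC assignments from annotation tables
#'
#' Each source table (e.g. the reference model's GPR-derived annotations,
#' Uniprot, NCBI Protein Clusters, RAST) maps genes to EC numbers. Only
#' fully specified EC numbers are kept -- four numeric fields, no dashes --
#' because wildcard ECs pull unrelated reactions into a draft; non-specific
#' entries are dropped with a warning.
#'
#' @param tables named list, one element per source: either a path to a TSV
#'   with columns `gene` and `ec` (semicolon-separated) or a data.frame
#'   with those columns.
#' @param sources source names; defaults to `names(tables)`.
#' @return data.frame with one row per (gene, source, ec) claim.
#' @export
collect_ec_assignments <- function(tables, sources = names(tables)) {
  if (is.null(sources) || any(!nzchar(sources))) {
    stop("annotation sources must be named")
  }
  out <- list()
  for (k in seq_along(tables)) {
    tab <- tables[[k]]
    if (is.character(tab)) tab <- read_tsv(tab)
    if (!all(c("gene", "ec") %in% names(tab))) {
      stop("annotation table '", sources[k], "' lacks gene/ec columns")
    }
    if (nrow(tab) == 0) next
    for (i in seq_len(nrow(tab))) {
      ecs <- split_field(tab$ec[i])
      spec <- is_specific_ec(ecs)
      if (any(!spec)) {
        warning("dropping non-specific EC(s) for gene ", tab$gene[i],
                " (", sources[k], "): ", paste(ecs[!spec], collapse = ", "),
                call. = FALSE)
      }
      ecs <- ecs[spec]
      if (length(ecs)) {
        out[[length(out) + 1L]] <- data.frame(
          gene = tab$gene[i], source = sources[k], ec = ecs,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(gene = character(0), source = character(0),
                      ec = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  unique(res)
}

is_specific_ec <- function(ec) {
  grepl("^[0-9]+\\.[0-9]+\\.[0-9]+\\.[0-9]+$", ec)
}

#' EC transfer history table
#'
#' The Enzyme Commission occasionally transfers an EC number to a new one;
#' annotations citing the old number must be mapped forward before they are
#' compared across sources (e.g. 2.5.1.8 was transferred to 2.5.1.75).
#' The table is transitively closed at load and must be acyclic.
#'
#' @param x path to a TSV with columns `old`, `new`, or a data.frame.
#' @return named character vector (old EC -> final EC), transitively closed.
#' @export
ec_transfer_table <- function(x) {
  if (is.character(x)) x <- read_tsv(x)
  if (nrow(x) == 0) return(stats::setNames(character(0), character(0)))
  if (!all(c("old", "new") %in% names(x))) {
    stop("EC transfer table needs columns old, new")
  }
  map <- stats::setNames(as.character(x$new), as.character(x$old))
  if (anyDuplicated(names(map))) stop("EC transfer table maps one EC twice")
  closed <- map
  for (from in names(map)) {
    seen <- from
    to <- map[[from]]
    while (to %in% names(map)) {
      if (to %in% seen) stop("cycle in EC transfer table involving ", to)
      seen <- c(seen, to)
      to <- map[[to]]
    }
    closed[[from]] <- to
  }
  closed
}

#' Normalise EC claims through the transfer table
#'
#' @param assignments data.frame from [collect_ec_assignments()].
#' @param table closed lookup from [ec_transfer_table()].
#' @return the assignments with transferred ECs replaced by their current
#'   numbers (lookup is idempotent); duplicates created by the mapping are
#'   collapsed.
#' @export
normalize_ecs <- function(assignments, table) {
  hit <- assignments$ec %in% names(table)
  assignments$ec[hit] <- unname(table[assignments$ec[hit]])
  unique(assignments)
}

#' Resolve conflicting EC annotations across sources
#'
#' Implements the ordered reconciliation procedure used when sources
#' disagree about a gene's enzymatic function:
#'
#' 1. EC numbers are mapped through the transfer history (step
#'    `ec_transfer`), which dissolves apparent conflicts between old and
#'    new numbers for the same enzyme.
#' 2. If every EC proposed by the non-reference sources is contained in
#'    the reference model's EC set for the gene, the gene is not treated
#'    as conflicting and the reference set is used (step `subset_rule`).
#' 3. ECs ruled out by curated external evidence -- e.g. an enzyme family
#'    restricted to a taxon the organism does not belong to -- are removed
#'    (step `evidence_exclusion`).
#' 4. ECs flagged as acting on generic metabolites, or on metabolites
#'    known to be absent from the organism, are removed (step
#'    `generic_metabolite`).
#' 5. Any remaining disagreement is settled by the confidence order,
#'    highest first (step `confidence_order`).
#'
#' @param assignments data.frame of claims (gene, source, ec), already
#'   collected via [collect_ec_assignments()].
#' @param order character vector of source names, highest confidence
#'   first; the first entry is taken to be the reference model. Every
#'   source present in `assignments` must be listed.
#' @param exclusions `NULL`, or a data.frame with columns `ec`, optional
#'   `gene` (empty/NA = applies to all genes) and `reason`, representing
#'   the curated literature/InterPro evidence file.
#' @param generic_ecs character vector of ECs tied to generic or absent
#'   metabolites.
#' @param transfer_table optional [ec_transfer_table()] lookup; when
#'   supplied, normalisation is performed (and recorded) here.
#' @return an `ec_resolution`: list of per-gene records with fields
#'   `gene`, `claims` (named list source -> ECs), `steps`, `resolved`,
#'   `basis` (`agreement`, `subset_rule`, `confidence_order`, or `empty`)
#'   and `conflicting`.
#' @export
resolve_conflicts <- function(assignments, order = c("reference", "uniprot",
                                                     "ncbi", "rast"),
                              exclusions = NULL, generic_ecs = character(0),
                              transfer_table = NULL) {
  missing_src <- setdiff(unique(assignments$source), order)
  if (length(missing_src)) {
    stop("source(s) absent from confidence order: ",
         paste(missing_src, collapse = ", "))
  }
  if (is.character(exclusions)) exclusions <- read_tsv(exclusions)
  records <- list()
  for (g in unique(assignments$gene)) {
    sub <- assignments[assignments$gene == g, , drop = FALSE]
    steps <- character(0)
    if (!is.null(transfer_table)) {
      before <- sub$ec
      sub <- normalize_ecs(sub, transfer_table)
      if (!setequal(before, sub$ec)) steps <- c(steps, "ec_transfer")
    }
    claims <- lapply(split(sub$ec, sub$source), function(e) sort(unique(e)))
    claims <- claims[intersect(order, names(claims))]
    rec <- resolve_gene(g, claims, order, exclusions, generic_ecs, steps)
    records[[g]] <- rec
  }
  structure(records, class = "ec_resolution")
}

resolve_gene <- function(gene, claims, order, exclusions, generic_ecs, steps) {
  agree <- function(cl) {
    cl <- cl[lengths(cl) > 0]
    length(cl) == 0 || all(vapply(cl, setequal, logical(1), y = cl[[1]]))
  }
  make <- function(resolved, basis, steps, conflicting) {
    list(gene = gene, claims = claims, steps = steps,
         resolved = sort(unique(resolved)), basis = basis,
         conflicting = conflicting)
  }
  ref_src <- order[1]
  excluded <- character(0)
  if (!is.null(exclusions) && nrow(exclusions)) {
    gene_col <- if ("gene" %in% names(exclusions)) exclusions$gene else NA
    applies <- is.na(gene_col) | !nzchar(ifelse(is.na(gene_col), "", gene_col)) |
      gene_col == gene
    excluded <- exclusions$ec[applies]
  }
  # resolved sets never carry excluded or generic-flagged ECs, whatever
  # route produced them
  finalize <- function(resolved, basis, steps, conflicting) {
    kept <- setdiff(resolved, c(excluded, generic_ecs))
    if (length(kept) < length(resolved)) {
      if (any(resolved %in% excluded)) steps <- union(steps, "evidence_exclusion")
      if (any(resolved %in% generic_ecs)) steps <- union(steps, "generic_metabolite")
    }
    if (length(kept) == 0 && length(resolved) > 0) {
      message("gene ", gene, ": no EC claims survive filtering")
      basis <- "empty"
    }
    make(kept, basis, steps, conflicting)
  }
  if (agree(claims)) {
    resolved <- if (length(claims)) claims[[1]] else character(0)
    return(finalize(resolved,
                    if (length(steps)) "agreement_after_transfer" else "agreement",
                    steps, conflicting = FALSE))
  }
  # subset rule: every non-reference claim contained in the reference set
  if (ref_src %in% names(claims)) {
    others <- unlist(claims[setdiff(names(claims), ref_src)], use.names = FALSE)
    if (length(others) && all(others %in% claims[[ref_src]])) {
      return(finalize(claims[[ref_src]], "subset_rule",
                      c(steps, "subset_rule"), conflicting = FALSE))
    }
  }
  filtered <- claims
  drop_from <- function(cl, bad) lapply(cl, function(e) setdiff(e, bad))
  if (length(excluded)) {
    after <- drop_from(filtered, excluded)
    if (!identical(after, filtered)) steps <- c(steps, "evidence_exclusion")
    filtered <- after
  }
  if (length(generic_ecs)) {
    after <- drop_from(filtered, generic_ecs)
    if (!identical(after, filtered)) steps <- c(steps, "generic_metabolite")
    filtered <- after
  }
  if (agree(filtered)) {
    nonempty <- filtered[lengths(filtered) > 0]
    if (length(nonempty) == 0) {
      message("gene ", gene, ": no EC claims survive filtering")
      return(make(character(0), "empty", steps, conflicting = TRUE))
    }
    return(make(nonempty[[1]], "agreement", steps, conflicting = TRUE))
  }
  steps <- c(steps, "confidence_order")
  for (src in order) {
    if (src %in% names(filtered) && length(filtered[[src]])) {
      return(make(filtered[[src]], "confidence_order", steps, conflicting = TRUE))
    }
  }
  make(character(0), "empty", steps, conflicting = TRUE)
}

#' @export
print.ec_resolution <- function(x, ...) {
  cat("<ec_resolution> ", length(x), " genes, ",
      sum(vapply(x, `[[`, TRUE, "conflicting")), " conflicting\n", sep = "")
  invisible(x)
}

#' Resolved EC sets
#' @param resolution an `ec_resolution` from [resolve_conflicts()].
#' @return named list gene -> resolved EC character vector.
#' @export
resolved_ecs <- function(resolution) {
  lapply(resolution, `[[`, "resolved")
}

#' @rdname resolved_ecs
#' @return `resolution_table()`: one-row-per-gene summary data.frame.
#' @export
resolution_table <- function(resolution) {
  data.frame(
    gene = vapply(resolution, `[[`, "", "gene"),
    resolved = vapply(resolution, function(r) paste(r$resolved, collapse = ";"), ""),
    basis = vapply(resolution, `[[`, "", "basis"),
    steps = vapply(resolution, function(r) paste(r$steps, collapse = ","), ""),
    conflicting = vapply(resolution, `[[`, TRUE, "conflicting"),
    stringsAsFactors = FALSE, row.names = NULL)
}
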