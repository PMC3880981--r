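#' Homology-based reaction transfer
#'
#' A reference reaction is transferred to the target organism when its GPR
#' evaluates true under the set of reference genes that have orthologs:
#' one satisfied isozyme (OR branch) suffices, while every subunit of a
#' complex (AND) must have an ortholog. Transferred GPRs are rewritten in
#' target gene ids; unsatisfied branches are pruned rather than carried
#' with placeholder genes.
#'
#' @name gpr_transfer
NULL

#' Translate a GPR to target gene identifiers
#'
#' Every complete complex or satisfied isozyme branch is rewritten using
#' the ortholog map; an AND branch containing any unmapped gene is pruned.
#' The GPR must be satisfied under the mapped genes (i.e. the reaction
#' transfers), otherwise this is a contract error.
#'
#' @param gpr a `gpr` tree (see [parse_gpr()]).
#' @param map an `ortholog_map` or named character vector
#'   (reference gene -> target gene).
#' @return the translated `gpr` tree.
#' @export
translate_gpr <- function(gpr, map) {
  if (inherits(map, "ortholog_map")) map <- map_as_vector(map)
  out <- prune_translate(gpr, map)
  if (is.null(out)) {
    stop("translate_gpr(): GPR is not satisfied under the ortholog map: ",
         deparse_gpr(gpr))
  }
  out
}

prune_translate <- function(gpr, map) {
  if (is.null(gpr)) return(NULL)
  if (is_gpr_leaf(gpr)) {
    if (gpr$gene %in% names(map)) return(gpr_leaf(unname(map[[gpr$gene]])))
    return(NULL)
  }
  kids <- lapply(gpr$args, prune_translate, map = map)
  ok <- !vapply(kids, is.null, logical(1))
  if (gpr$op == "and") {
    if (!all(ok)) return(NULL)
    kept <- kids
  } else {
    if (!any(ok)) return(NULL)
    kept <- kids[ok]
  }
  if (length(kept) == 1L) kept[[1]] else gpr_node(gpr$op, kept)
}

#' Transfer reactions from a reference model under an ortholog map
#'
#' Evaluates every GPR-bearing reference reaction under the mapped
#' reference genes; satisfied reactions are copied with GPRs translated to
#' target gene ids and provenance `"reference_transfer"`. Reactions with an
#' empty GPR are never transferred here -- they are candidates for the
#' essential-append and gapfilling stages, which carry their own evidence.
#'
#' @param ref reference [metabolic_model()].
#' @param map an `ortholog_map` (or named vector reference -> target gene).
#' @return list of transferred [reaction()] objects.
#' @export
transfer_reactions <- function(ref, map) {
  if (inherits(map, "ortholog_map")) map <- map_as_vector(map)
  present <- names(map)
  out <- list()
  for (r in ref$reactions) {
    if (is.null(r$gpr)) next
    if (!evaluate_gpr(r$gpr, present)) next
    r$gpr <- translate_gpr(r$gpr, map)
    r$provenance <- "reference_transfer"
    out[[r$id]] <- r
  }
  out
}
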