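#' Build a GPR from annotation designations (Autograph-style)
#'
#' For a reaction retrieved from the universal database, all genes linked
#' to its EC number by annotations contribute to the GPR. Genes sharing
#' the same functional designation string are taken to be isozymes (OR);
#' genes with different designations are taken to be subunits of one
#' complex (AND across designation groups, OR within a group).
#' Designations are compared after lower-casing and whitespace
#' normalisation; a gene listed under two designations joins both groups.
#'
#' @param gene_designations data.frame with columns `gene` and
#'   `designation` (the annotation's functional name string, preferably
#'   from a single consistent source such as RAST).
#' @return a `gpr` tree, or `NULL` when no genes are given.
#' @export
build_gpr_from_annotations <- function(gene_designations) {
  if (is.null(gene_designations) || nrow(gene_designations) == 0) return(NULL)
  des <- normalize_designation(gene_designations$designation)
  groups <- split(gene_designations$gene, des)
  groups <- groups[order(names(groups))]
  group_nodes <- lapply(groups, function(genes) {
    genes <- sort(unique(genes))
    leaves <- lapply(genes, gpr_leaf)
    if (length(leaves) == 1L) leaves[[1]] else gpr_node("or", leaves)
  })
  if (length(group_nodes) == 1L) group_nodes[[1]] else gpr_node("and", unname(group_nodes))
}

normalize_designation <- function(x) {
  tolower(gsub("[[:space:]]+", " ", trimws(x)))
}

#' Complete missing GPRs with a relaxed ortholog pass
#'
#' Reactions taken from the reference for reasons other than homology
#' (photosynthesis evidence, biomass necessity) often miss a small number
#' of best hits at the strict cutoff. A second ortholog map computed at a
#' relaxed e-value cutoff (the workflow uses 1e-10) is merged over the
#' strict map; reference GPRs that become satisfiable are translated and
#' attached. Existing GPRs are never overwritten.
#'
#' @param model draft [metabolic_model()] (reactions lacking GPRs keep
#'   reference ids).
#' @param ref reference [metabolic_model()] supplying the original GPRs.
#' @param strict_map,relaxed_map `ortholog_map`s (or named vectors); the
#'   relaxed map fills genes absent from the strict one.
#' @return list with the updated `model` and `unresolved` -- ids of
#'   reactions whose reference GPR still cannot be satisfied.
#' @export
complete_missing_gprs <- function(model, ref, strict_map, relaxed_map) {
  to_vec <- function(m) if (inherits(m, "ortholog_map")) map_as_vector(m) else m
  strict <- to_vec(strict_map)
  relaxed <- to_vec(relaxed_map)
  merged <- c(strict, relaxed[setdiff(names(relaxed), names(strict))])
  unresolved <- character(0)
  for (id in reaction_ids(model)) {
    r <- model$reactions[[id]]
    if (!is.null(r$gpr)) next
    ref_gpr <- if (id %in% reaction_ids(ref)) ref$reactions[[id]]$gpr else NULL
    if (is.null(ref_gpr)) {
      unresolved <- c(unresolved, id)
      next
    }
    if (evaluate_gpr(ref_gpr, names(merged))) {
      model$reactions[[id]]$gpr <- translate_gpr(ref_gpr, merged)
    } else {
      unresolved <- c(unresolved, id)
    }
  }
  list(model = model, unresolved = unresolved)
}
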