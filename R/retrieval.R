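#' Match resolved ECs against the reference model
#'
#' Resolved EC numbers are referenced against the curated model first:
#' reactions carrying a matching EC are retained from there (with their
#' richer GPR and compartment information), and only the leftover ECs go
#' on to database retrieval.
#'
#' @param ecs character vector of resolved EC numbers.
#' @param ref reference [metabolic_model()].
#' @return list with `reactions` (matched reference [reaction()]s) and
#'   `leftover` (ECs with no reference match); the EC partition is exact
#'   and disjoint.
#' @export
match_ec_to_reference <- function(ecs, ref) {
  ecs <- unique(ecs)
  matched <- list()
  hit <- character(0)
  for (r in ref$reactions) {
    if (length(intersect(r$ec, ecs))) {
      matched[[r$id]] <- r
      hit <- union(hit, intersect(r$ec, ecs))
    }
  }
  list(reactions = matched, leftover = setdiff(ecs, hit))
}

#' Retrieve reactions from a universal (SEED-like) database by EC
#'
#' Only database entries flagged as balanced are eligible -- the analogue
#' of restricting to the charge- and elementally-balanced subset a
#' gapfilling service would use. Unmatched ECs are reported so they can be
#' compiled for curation.
#'
#' @param ecs character vector of EC numbers still without a reaction.
#' @param db universal reaction database: a [metabolic_model()] read from
#'   the tabular dialect, or a list of [reaction()]s each carrying a
#'   `balanced` flag in `$sources` handling or via attribute; entries with
#'   provenance `"seed_retrieval"` are assumed balanced when no flag is
#'   present.
#' @param balanced named logical vector (reaction id -> balanced), or
#'   `NULL` to use the `balanced` column carried by [read_universal_db()].
#' @return list with `reactions` (provenance set to `"seed_retrieval"`)
#'   and `unmatched` ECs.
#' @export
retrieve_seed_reactions <- function(ecs, db, balanced = NULL) {
  ecs <- unique(ecs)
  rxns <- if (inherits(db, "metabolic_model")) db$reactions else db
  if (is.null(balanced)) {
    balanced <- vapply(rxns, function(r) !isFALSE(attr(r, "balanced")), logical(1))
    names(balanced) <- vapply(rxns, `[[`, "", "id")
  }
  out <- list()
  hit <- character(0)
  for (r in rxns) {
    if (!isTRUE(balanced[[r$id]])) next
    common <- intersect(r$ec, ecs)
    if (length(common)) {
      r$provenance <- "seed_retrieval"
      out[[r$id]] <- r
      hit <- union(hit, common)
    }
  }
  list(reactions = out, unmatched = setdiff(ecs, hit))
}

#' Read a universal reaction database from the tabular dialect
#'
#' Same format as a tabular model's `reactions.tsv` plus an optional
#' `balanced` 0/1 column (default 1). ΔG and its error ride in the `dG` /
#' `dG_err` columns (kcal/mol).
#'
#' @param path path to the TSV (or a directory containing `reactions.tsv`).
#' @param metabolites optional metabolite table for generic flags.
#' @return list of [reaction()]s with a `balanced` attribute each.
#' @export
read_universal_db <- function(path, metabolites = NULL) {
  file <- if (dir.exists(path)) file.path(path, "reactions.tsv") else path
  tab <- read_tsv(file)
  model <- model_from_tables("universal_db", tab, metabolites)
  rxns <- model$reactions
  bal <- if ("balanced" %in% names(tab)) as.logical(tab$balanced) else rep(TRUE, nrow(tab))
  names(bal) <- tab$id
  for (id in names(rxns)) attr(rxns[[id]], "balanced") <- isTRUE(bal[[id]])
  rxns
}

#' Filter reactions touching generic metabolites
#'
#' Generic metabolites (non-specific acceptors, generalised lipids, or
#' compounds known to be absent from the organism) pull spurious chemistry
#' into a draft; any reaction involving one is removed and logged.
#'
#' @param reactions list of [reaction()]s.
#' @param metabolites metabolite table carrying `is_generic`; ids absent
#'   from the table are treated as specific.
#' @return list with `kept` and `removed` reaction lists.
#' @export
filter_generic <- function(reactions, metabolites) {
  generic_ids <- metabolites$id[metabolites$is_generic %in% TRUE]
  touches <- vapply(reactions, function(r) any(names(r$stoich) %in% generic_ids),
                    logical(1))
  list(kept = reactions[!touches], removed = reactions[touches])
}

#' Append essential reference reactions by category
#'
#' Photosynthesis reactions are known to exist in any organism that grows
#' autotrophically; oxidative phosphorylation and diffusion transport
#' reactions are appended for their obvious essentiality. Reactions whose
#' stoichiometry is already present (under [canonical_stoich_key()]) are
#' not duplicated -- the copy already in the draft wins.
#'
#' @param draft list of [reaction()]s assembled so far.
#' @param ref reference [metabolic_model()] with `subsystem` tags.
#' @param categories subsystem tags to append; default the three
#'   essential classes.
#' @return the extended reaction list; appended copies carry provenance
#'   `"essential_append"`.
#' @export
append_essential <- function(draft, ref,
                             categories = c("photosynthesis",
                                            "oxidative_phosphorylation",
                                            "diffusion_transport")) {
  have_ids <- vapply(draft, `[[`, "", "id")
  for (r in ref$reactions) {
    if (is.na(r$subsystem) || !r$subsystem %in% categories) next
    if (r$id %in% have_ids) next
    r$provenance <- "essential_append"
    draft[[r$id]] <- r
    have_ids <- c(have_ids, r$id)
  }
  # same-stoichiometry duplicates collapse onto the reference-derived copy
  dedupe_reactions(draft)
}

#' Deduplicate an assembled reaction list
#'
#' Keeps one representative per canonical stoichiometry, preferring
#' provenance in the order reference transfer, essential append, SEED
#' retrieval, gapfill addition (the reference copy carries the curated
#' GPR and compartment assignment).
#'
#' @param reactions list of [reaction()]s.
#' @return deduplicated list.
#' @export
dedupe_reactions <- function(reactions) {
  if (length(reactions) == 0) return(reactions)
  pref <- c(reference = 0, reference_transfer = 0, essential_append = 1,
            seed_retrieval = 2, gapfill_addition = 3)
  keys <- vapply(reactions, function(r) canonical_stoich_key(r$stoich), "")
  rank <- vapply(reactions, function(r) {
    p <- unname(pref[r$provenance])
    if (is.na(p)) 4 else p
  }, numeric(1))
  ord <- order(keys, rank)
  keep <- ord[!duplicated(keys[ord])]
  reactions[sort(keep)]
}
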