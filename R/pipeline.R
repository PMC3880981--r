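#' Run the full reconstruction workflow
#'
#' Orchestrates draft construction, gapfilling and cycle repair:
#'
#' 1. Parse BLAST tables; compute strict (default 1e-30) and relaxed
#'    (default 1e-10) bidirectional-best-hit ortholog maps.
#' 2. Transfer reference reactions whose GPRs are satisfied under the
#'    strict map, with GPRs translated to target gene ids.
#' 3. Collect gene-to-EC annotations from all sources (the reference
#'    model's own claims are derived from its GPRs through the ortholog
#'    map), normalise through the EC transfer history, and resolve
#'    conflicts by the ordered procedure of [resolve_conflicts()].
#' 4. Match resolved ECs against the reference first, then retrieve the
#'    leftovers from the balanced universal database; build Autograph
#'    GPRs for retrieved reactions from shared annotation designations.
#' 5. Filter reactions touching generic metabolites; append essential
#'    photosynthesis / oxidative-phosphorylation / diffusion-transport
#'    reactions; deduplicate; add the reference biomass drain.
#' 6. For each growth condition, find a minimal gapfill set from the
#'    non-transferred reference reactions (enumerating alternatives
#'    within `alt_slack` of the minimum and preferring the set with most
#'    annotation evidence), and add the union.
#' 7. Remove thermodynamically infeasible cycles with [repair_cycles()].
#' 8. Complete missing GPRs with the relaxed ortholog pass.
#'
#' @param config path to a YAML config (paths resolved relative to it) or
#'   an equivalent named list (paths then resolved against `base_dir`).
#'   See the fixture bundle's `config.yaml` for the schema.
#' @param base_dir base directory for relative paths when `config` is a
#'   list.
#' @return a `reconstruction` list: `draft`, `gapfilled`, `final` models,
#'   `maps` (strict/relaxed), `resolution`, and `reports` (unmatched ECs,
#'   removed generic reactions, gapfill additions per condition with
#'   evidence status, cycle modification log, unresolved GPRs). Output
#'   files are written under the configured `output_dir`.
#' @export
run_reconstruction <- function(config, base_dir = ".") {
  if (is.character(config)) {
    base_dir <- dirname(config)
    config <- yaml::read_yaml(config)
  }
  pth <- function(x) if (is.null(x)) NULL else file.path(base_dir, x)
  need <- c("reference", "blast", "annotations", "universal_db", "conditions")
  miss <- setdiff(need, names(config))
  if (length(miss)) stop("config lacks required entr(ies): ", paste(miss, collapse = ", "))
  th <- utils::modifyList(
    list(evalue_strict = 1e-30, evalue_relaxed = 1e-10,
         biomass_floor_frac = 0.01, dg_threshold = 4, alt_slack = 2),
    if (is.null(config$thresholds)) list() else config$thresholds)
  for (f in c(pth(config$reference), pth(config$blast$fwd), pth(config$blast$rev),
              unlist(pth(config$annotations)), pth(config$universal_db))) {
    if (!file.exists(f)) stop("configured input does not exist: ", f)
  }

  ref <- read_model(pth(config$reference), id = "reference")
  fwd <- parse_blast_tabular(pth(config$blast$fwd))
  rev <- parse_blast_tabular(pth(config$blast$rev))
  strict_map <- ortholog_map(fwd, rev, cutoff = th$evalue_strict)
  relaxed_map <- ortholog_map(fwd, rev, cutoff = th$evalue_relaxed)

  transferred <- transfer_reactions(ref, strict_map)

  tables <- lapply(config$annotations, function(x) read_tsv(file.path(base_dir, x)))
  order <- if (is.null(config$confidence_order)) {
    c("reference", names(tables))
  } else unlist(config$confidence_order)
  ref_claims <- reference_ec_table(ref, strict_map)
  if (!is.null(config$reference_annotations_extra)) {
    extra <- read_tsv(pth(config$reference_annotations_extra))
    ref_claims <- rbind(ref_claims, extra[c("gene", "ec")])
  }
  assignments <- collect_ec_assignments(
    c(list(reference = ref_claims), tables),
    sources = c("reference", names(tables)))
  transfer_tab <- if (is.null(config$ec_transfer)) NULL else ec_transfer_table(pth(config$ec_transfer))
  exclusions <- if (is.null(config$exclusions)) NULL else read_tsv(pth(config$exclusions))
  generic_ecs <- if (is.null(config$generic_ecs)) character(0) else readLines(pth(config$generic_ecs))
  resolution <- resolve_conflicts(assignments, order = order,
                                  exclusions = exclusions,
                                  generic_ecs = generic_ecs,
                                  transfer_table = transfer_tab)
  all_ecs <- sort(unique(unlist(resolved_ecs(resolution))))

  ref_match <- match_ec_to_reference(all_ecs, ref)
  db <- read_universal_db(pth(config$universal_db))
  seed_got <- retrieve_seed_reactions(ref_match$leftover, db)
  seed_rxns <- annotate_seed_reactions(seed_got$reactions, resolution,
                                       assignments, tables)

  draft_rxns <- transferred
  for (r in ref_match$reactions) {
    if (r$id %in% names(draft_rxns)) next
    r$provenance <- "reference_transfer"
    # curated GPR kept only when satisfied by the ortholog map
    r$gpr <- if (!is.null(r$gpr) &&
                 evaluate_gpr(r$gpr, strict_map$ref)) {
      translate_gpr(r$gpr, strict_map)
    } else NULL
    draft_rxns[[r$id]] <- r
  }
  draft_rxns <- c(draft_rxns, seed_rxns[setdiff(names(seed_rxns), names(draft_rxns))])

  db_mets <- do.call(rbind, lapply(sort(unique(unlist(
    lapply(db, function(r) names(r$stoich))))), metabolite))
  all_mets <- rbind(ref$metabolites,
                    db_mets[!db_mets$id %in% ref$metabolites$id, , drop = FALSE])
  flt <- filter_generic(draft_rxns, all_mets)
  draft_rxns <- append_essential(flt$kept, ref)
  draft_rxns <- dedupe_reactions(draft_rxns)
  for (b in ref$biomass) {
    if (!b %in% names(draft_rxns)) draft_rxns[[b]] <- ref$reactions[[b]]
  }
  draft <- metabolic_model("draft", used_metabolites(draft_rxns, all_mets),
                           draft_rxns, biomass = ref$biomass)

  candidates <- ref$reactions[setdiff(reaction_ids(ref), reaction_ids(draft))]
  gap_reports <- list()
  chosen <- character(0)
  for (cond_name in names(config$conditions)) {
    cond <- lapply(config$conditions[[cond_name]], as.numeric)
    model_cond <- draft
    if (length(chosen)) model_cond <- add_reactions(model_cond, lapply(
      candidates[chosen], set_provenance, "gapfill_addition"))
    cand_cond <- candidates[setdiff(names(candidates), chosen)]
    prob <- gapfill_problem(model_cond, unname(cand_cond),
                            floor_frac = th$biomass_floor_frac,
                            bounds = cond[names(cond) %in% reaction_ids(model_cond) |
                                            names(cond) %in% names(cand_cond)])
    alts <- enumerate_alternatives(prob, slack = th$alt_slack)
    if (alts$status != "optimal") {
      gap_reports[[cond_name]] <- list(status = alts$status, additions = character(0),
                                       blocked = if (!prob$feasible)
                                         diagnose_blocked_precursors(prob) else character(0))
      next
    }
    pick <- choose_gapfill_solution(alts$sets, ref, all_ecs)
    gap_reports[[cond_name]] <- list(
      status = "optimal", minimum = alts$minimum, n_alternatives = length(alts$sets),
      additions = pick$set, evidence = pick$evidence)
    chosen <- union(chosen, pick$set)
  }
  gapfilled <- if (length(chosen)) {
    add_reactions(draft, lapply(candidates[chosen], set_provenance,
                                "gapfill_addition"))
  } else draft
  gapfilled$id <- "gapfilled"

  rep_out <- repair_cycles(gapfilled, dg_threshold = th$dg_threshold)
  final <- rep_out$model
  final$id <- "final"
  compl <- complete_missing_gprs(final, ref, strict_map, relaxed_map)
  final <- compl$model
  # exchanges and the biomass pseudo-reaction never carry genes
  unresolved <- setdiff(compl$unresolved,
                        c(names(which(is_exchange(final))), final$biomass))

  reports <- list(
    unmatched_ecs = seed_got$unmatched,
    removed_generic = vapply(flt$removed, `[[`, "", "id"),
    gapfill = gap_reports,
    cycle_log = rep_out$log,
    unrepairable_cycles = rep_out$unrepairable,
    unresolved_gprs = unresolved,
    resolution = resolution_table(resolution))

  out_dir <- pth(if (is.null(config$output_dir)) "out" else config$output_dir)
  write_outputs(out_dir, draft, gapfilled, final, reports)
  structure(list(draft = draft, gapfilled = gapfilled, final = final,
                 maps = list(strict = strict_map, relaxed = relaxed_map),
                 resolution = resolution, reports = reports,
                 conditions = lapply(config$conditions,
                                     function(x) lapply(x, as.numeric)),
                 output_dir = out_dir),
            class = "reconstruction")
}

set_provenance <- function(r, p) { r$provenance <- p; r }

used_metabolites <- function(rxns, mets) {
  ids <- sort(unique(unlist(lapply(rxns, function(r) names(r$stoich)))))
  extra <- setdiff(ids, mets$id)
  if (length(extra)) mets <- rbind(mets, do.call(rbind, lapply(extra, metabolite)))
  mets[mets$id %in% ids, , drop = FALSE]
}

#' Reference-model EC claims on target gene ids
#'
#' The reference model is itself an annotation source: a target gene with
#' an ortholog to reference gene g claims the ECs of every reference
#' reaction whose GPR mentions g.
#'
#' @param ref reference [metabolic_model()].
#' @param map an `ortholog_map`.
#' @return data.frame with columns `gene`, `ec`.
#' @export
reference_ec_table <- function(ref, map) {
  vec <- map_as_vector(map)
  rows <- list()
  for (r in ref$reactions) {
    if (is.null(r$gpr) || length(r$ec) == 0) next
    for (g in intersect(gpr_genes(r$gpr), names(vec))) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene = vec[[g]], ec = paste(r$ec, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(gene = character(0), ec = character(0),
                      stringsAsFactors = FALSE))
  }
  unique(do.call(rbind, rows))
}

annotate_seed_reactions <- function(rxns, resolution, assignments, tables) {
  res <- resolved_ecs(resolution)
  # genes supporting each EC after resolution
  genes_of_ec <- list()
  for (g in names(res)) for (e in res[[g]]) genes_of_ec[[e]] <- union(genes_of_ec[[e]], g)
  rast_des <- NULL
  if ("rast" %in% names(tables) && "designation" %in% names(tables$rast)) {
    rast_des <- tables$rast
  }
  for (id in names(rxns)) {
    r <- rxns[[id]]
    genes <- sort(unique(unlist(genes_of_ec[r$ec])))
    srcs <- unique(assignments$source[assignments$gene %in% genes &
                                        assignments$ec %in% r$ec])
    rxns[[id]]$sources <- sort(setdiff(srcs, "reference"))
    if (length(genes) && !is.null(rast_des)) {
      des <- rast_des[rast_des$gene %in% genes, c("gene", "designation")]
      des <- des[!is.na(des$designation), , drop = FALSE]
      if (nrow(des)) rxns[[id]]$gpr <- build_gpr_from_annotations(des)
    }
  }
  rxns
}

#' Pick a gapfill solution by annotation evidence
#'
#' Among the enumerated alternative sets, the one containing the most
#' reactions with supporting evidence (a GPR in the reference model or a
#' resolved EC) is chosen; ties go to the smaller, then lexicographically
#' first, set.
#'
#' @param sets list of candidate-id vectors from
#'   [enumerate_alternatives()].
#' @param ref reference [metabolic_model()].
#' @param resolved_ec_set character vector of resolved ECs.
#' @return list with `set` and `evidence` (named logical per member).
#' @export
choose_gapfill_solution <- function(sets, ref, resolved_ec_set) {
  stopifnot(length(sets) > 0)
  evidence_of <- function(ids) {
    vapply(ids, function(id) {
      r <- ref$reactions[[id]]
      !is.null(r$gpr) || length(intersect(r$ec, resolved_ec_set)) > 0
    }, logical(1))
  }
  ev <- lapply(sets, evidence_of)
  score <- vapply(ev, sum, 0)
  ord <- order(-score, lengths(sets), vapply(sets, paste, "", collapse = ","))
  list(set = sets[[ord[1]]], evidence = ev[[ord[1]]])
}

write_outputs <- function(out_dir, draft, gapfilled, final, reports) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_model(draft, file.path(out_dir, "draft"), format = "tabular")
  write_model(gapfilled, file.path(out_dir, "gapfilled"), format = "tabular")
  write_model(final, file.path(out_dir, "final"), format = "tabular")
  write_model(final, file.path(out_dir, "final.xml"), format = "sbml")
  wl <- function(x, f) writeLines(as.character(x), file.path(out_dir, f))
  wl(reports$unmatched_ecs, "unmatched_ecs.txt")
  wl(reports$removed_generic, "removed_generic.txt")
  wl(reports$unresolved_gprs, "unresolved_gprs.txt")
  utils::write.table(reports$cycle_log, file.path(out_dir, "cycle_modifications.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(reports$resolution, file.path(out_dir, "ec_resolution.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(reports$gapfill, file.path(out_dir, "gapfill.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.reconstruction <- function(x, ...) {
  cat("<reconstruction>\n",
      "  draft:     ", n_reactions(x$draft), " reactions\n",
      "  gapfilled: ", n_reactions(x$gapfilled), " reactions\n",
      "  final:     ", n_reactions(x$final), " reactions\n",
      "  outputs:   ", x$output_dir, "\n", sep = "")
  invisible(x)
}
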