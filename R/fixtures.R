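#' Synthetic fixture generators
#'
#' Every input the reconstruction workflow consumes can be generated
#' synthetically with recorded ground truth: a curated reference model
#' with tagged essential subsystems and mixed AND/OR GPRs, a target
#' genome with planted mutual-best-hit orthologs and decoy BLAST hits
#' straddling both e-value cutoffs, multi-source annotation tables with
#' planted conflict archetypes, and a balanced universal reaction
#' database with an optional planted thermodynamically infeasible loop
#' and gapfill rescue reaction. All generators are deterministic per
#' seed.
#'
#' @name fixtures
NULL

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Generate a curated reference model
#'
#' Builds a small photoautotroph-style network: photon, CO2, O2, ammonium,
#' glucose and water exchanges; diffusion and carrier transports; a
#' photosystem reaction (tagged `photosynthesis`), respiration (tagged
#' `oxidative_phosphorylation`), carbon fixation, five biomass precursors
#' and a biomass drain; plus `n_rxns - 22` randomized side reactions.
#' Carrier transports and enzymatic steps carry GPRs of mixed AND/OR
#' structure over `n_genes` genes; exchanges, diffusion transports and
#' the biomass drain have no GPR, as in curated reconstructions.
#'
#' @param n_rxns total reaction count (>= 22, the core size).
#' @param n_genes number of genes available for GPRs.
#' @param seed RNG seed; generation is deterministic per seed.
#' @return a validated [metabolic_model()] that grows under the
#'   autotrophic condition of [autotrophic_condition()].
#' @export
make_reference_model <- function(n_rxns = 30, n_genes = 24, seed = 1) {
  stopifnot(n_rxns >= 22, n_genes >= 10)
  with_seed(seed, {
    genes <- sprintf("g%03d", seq_len(n_genes))
    gp <- function() random_gpr_string(genes)
    rx <- list()
    addr <- function(id, eq, lb = NULL, ub = NULL, gpr = "", ec = character(0),
                     subsystem = NA_character_) {
      rx[[id]] <<- reaction(id, equation = eq, lb = lb, ub = ub,
                            gpr = if (nzchar(gpr)) gpr else NULL, ec = ec,
                            provenance = "reference", subsystem = subsystem)
    }
    addr("EX_photon", "photon[e] <=>", lb = -100, subsystem = "exchange")
    addr("EX_co2", "co2[e] <=>", lb = -10, subsystem = "exchange")
    addr("EX_o2", "o2[e] <=>", lb = -10, subsystem = "exchange")
    addr("EX_nh4", "nh4[e] <=>", lb = -10, subsystem = "exchange")
    addr("EX_glc", "glc[e] <=>", lb = 0, subsystem = "exchange")
    addr("EX_h2o", "h2o[e] <=>", lb = -10, subsystem = "exchange")
    addr("T_photon", "photon[e] => photon[c]", subsystem = "diffusion_transport")
    addr("T_co2_ep", "co2[e] <=> co2[p]", subsystem = "diffusion_transport")
    addr("T_co2_pc", "co2[p] <=> co2[c]", subsystem = "diffusion_transport")
    addr("T_o2", "o2[e] <=> o2[c]", subsystem = "diffusion_transport")
    addr("T_h2o", "h2o[e] <=> h2o[c]", subsystem = "diffusion_transport")
    addr("T_nh4", "nh4[e] => nh4[c]", gpr = gp(), subsystem = "transport")
    addr("T_glc", "glc[e] => glc[c]", gpr = gp(), subsystem = "transport")
    addr("PSII", "2 photon[c] + h2o[c] => atp[c] + o2[c]",
         gpr = gp(), subsystem = "photosynthesis")
    addr("OXPHOS", "glc[c] + o2[c] => 2 atp[c] + co2[c]",
         gpr = gp(), ec = "1.9.3.1", subsystem = "oxidative_phosphorylation")
    addr("CBB", "co2[c] + atp[c] => cfix[c]", gpr = gp(), ec = "4.1.1.39")
    addr("GLY", "glc[c] + atp[c] => 2 cfix[c]", gpr = gp(), ec = "2.7.1.2")
    for (k in 1:5) {
      eq <- switch(k,
                   "cfix[c] + atp[c] => P1[c]",
                   "cfix[c] => P2[c]",
                   "2 cfix[c] => P3[c]",
                   "cfix[c] + atp[c] => P4[c]",
                   "cfix[c] + nh4[c] => P5[c]")
      addr(paste0("PS", k), eq, gpr = gp(), ec = sprintf("2.3.1.%d", 50 + k))
    }
    addr("BIOMASS",
         "0.2 P1[c] + 0.2 P2[c] + 0.2 P3[c] + 0.2 P4[c] + 0.2 P5[c] + atp[c] =>",
         subsystem = "biomass")
    pool <- c("P1[c]", "P2[c]", "P3[c]", "P4[c]", "P5[c]", "cfix[c]")
    for (k in seq_len(n_rxns - length(rx))) {
      src <- sample(pool, 1)
      addr(sprintf("SIDE%02d", k), sprintf("%s <=> side%02d[c]", src, k),
           gpr = gp(), ec = sprintf("5.3.1.%d", 100 + k))
    }
    met_ids <- sort(unique(unlist(lapply(rx, function(r) names(r$stoich)))))
    mets <- do.call(rbind, lapply(met_ids, metabolite))
    metabolic_model("reference", mets, rx, biomass = "BIOMASS",
                    compartments = c("c", "p", "e"))
  })
}

random_gpr_string <- function(genes) {
  form <- sample(c("single", "or2", "and2", "or3", "and_or", "or_and"), 1,
                 prob = c(0.3, 0.2, 0.2, 0.1, 0.1, 0.1))
  g <- sample(genes, 3)
  switch(form,
         single = g[1],
         or2 = sprintf("%s or %s", g[1], g[2]),
         and2 = sprintf("%s and %s", g[1], g[2]),
         or3 = sprintf("%s or %s or %s", g[1], g[2], g[3]),
         and_or = sprintf("(%s and %s) or %s", g[1], g[2], g[3]),
         or_and = sprintf("(%s or %s) and %s", g[1], g[2], g[3]))
}

#' Standard growth-condition bound sets for the fixture world
#'
#' @return named list of exchange-bound overrides (`reaction id ->
#'   c(lb, ub)`): photon/CO2-fed for autotrophic growth, glucose/O2-fed
#'   with the light and CO2 uptake closed for heterotrophic growth.
#' @export
autotrophic_condition <- function() {
  list(EX_photon = c(-100, 1000), EX_co2 = c(-10, 1000), EX_o2 = c(-10, 1000),
       EX_nh4 = c(-10, 1000), EX_glc = c(0, 1000), EX_h2o = c(-10, 1000))
}

#' @rdname autotrophic_condition
#' @export
heterotrophic_condition <- function() {
  list(EX_photon = c(0, 1000), EX_co2 = c(0, 1000), EX_o2 = c(-10, 1000),
       EX_nh4 = c(-10, 1000), EX_glc = c(-10, 1000), EX_h2o = c(-10, 1000))
}

#' Generate a target genome with planted orthologs and BLAST tables
#'
#' A chosen fraction of the reference genes get a target ortholog
#' (`t_<gene>`) planted as a mutual best hit below the strict cutoff;
#' a further fraction get only a relaxed-level mutual best hit (e-value
#' between 1e-30 and 1e-10, so it appears only in the relaxed pass);
#' decoy hits above both cutoffs and worse-ranked secondary hits exercise
#' the best-hit logic. Ground truth is recorded.
#'
#' @param ref reference [metabolic_model()].
#' @param ortholog_fraction fraction of reference genes with a strict
#'   ortholog.
#' @param relaxed_fraction fraction with only a relaxed-level ortholog.
#' @param seed RNG seed.
#' @return list with `genes` (target gene ids), `fwd`/`rev` BLAST hit
#'   data.frames (reference-vs-target / target-vs-reference), and `truth`
#'   (`strict` and `relaxed` ortholog data.frames with `ref`, `target`).
#' @export
make_target_genome <- function(ref, ortholog_fraction = 0.7,
                               relaxed_fraction = 0.15, seed = 1) {
  stopifnot(ortholog_fraction >= 0, ortholog_fraction <= 1)
  with_seed(seed, {
    genes <- model_genes(ref)
    n <- length(genes)
    n_strict <- round(ortholog_fraction * n)
    strict <- sort(sample(genes, n_strict))
    rest <- setdiff(genes, strict)
    n_relax <- min(length(rest), round(relaxed_fraction * n))
    relaxed <- sort(sample(rest, n_relax))
    fwd <- list(); rev <- list()
    mk <- function(q, s, ev) {
      pid <- round(stats::runif(1, 30, 65), 1)
      bits <- round(-10 * log10(ev) + stats::runif(1, 0, 20), 1)
      data.frame(query = q, subject = s, pct_identity = pid, length = 300L,
                 mismatch = 10L, gapopen = 1L, qstart = 1L, qend = 300L,
                 sstart = 1L, send = 300L, evalue = ev, bitscore = bits,
                 stringsAsFactors = FALSE)
    }
    t_of <- function(g) if (length(g) == 0) character(0) else paste0("t_", g)
    for (g in strict) {
      ev <- 10^stats::runif(1, -60, -35)
      fwd[[length(fwd) + 1L]] <- mk(g, t_of(g), ev)
      rev[[length(rev) + 1L]] <- mk(t_of(g), g, 10^stats::runif(1, -60, -35))
      if (stats::runif(1) < 0.3) {  # worse-ranked secondary hit, still below cutoff
        other <- t_of(sample(setdiff(strict, g), 1))
        fwd[[length(fwd) + 1L]] <- mk(g, other, ev * 10^stats::runif(1, 2, 5))
      }
    }
    for (g in relaxed) {
      ev <- 10^stats::runif(1, -25, -12)
      fwd[[length(fwd) + 1L]] <- mk(g, t_of(g), ev)
      rev[[length(rev) + 1L]] <- mk(t_of(g), g, 10^stats::runif(1, -25, -12))
    }
    for (g in setdiff(rest, relaxed)) {  # spurious similarity above both cutoffs
      fwd[[length(fwd) + 1L]] <- mk(g, t_of(sample(genes, 1)), 10^stats::runif(1, -8, -2))
    }
    bind <- function(x) if (length(x)) do.call(rbind, x) else mk("q", "s", 1)[0, ]
    list(genes = sort(t_of(c(strict, relaxed))),
         fwd = bind(fwd), rev = bind(rev),
         truth = list(
           strict = data.frame(ref = strict, target = t_of(strict),
                               stringsAsFactors = FALSE),
           relaxed = data.frame(ref = relaxed, target = t_of(relaxed),
                                stringsAsFactors = FALSE)))
  })
}

#' Write BLAST hits in 12-column tabular format
#' @param hits data.frame as produced by [make_target_genome()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_blast_tabular <- function(hits, path) {
  cols <- c("query", "subject", "pct_identity", "length", "mismatch",
            "gapopen", "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  missing <- setdiff(cols, names(hits))
  for (m in missing) hits[[m]] <- 0
  hits$evalue <- format(hits$evalue, scientific = TRUE, digits = 4)
  utils::write.table(hits[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Generate multi-source annotation tables with planted conflicts
#'
#' Builds Uniprot/NCBI/RAST-style gene-to-EC tables for the target
#' genome. Ortholog-backed genes inherit their reference reactions' ECs
#' (with per-source dropout so sources differ in coverage); a set of
#' novel ECs (matching universal-database entries) is spread over target
#' genes; loop-reaction ECs are claimed only by RAST. Conflict archetypes
#' are planted on dedicated synthetic genes, with the expected resolution
#' recorded:
#' \describe{
#'   \item{ec-transfer}{one source uses a superseded EC number that the
#'     transfer table maps onto the others' claim.}
#'   \item{evidence-exclusion}{an extra claim is ruled out by the curated
#'     exclusions table, the rest by confidence order.}
#'   \item{generic-metabolite}{a claim tied to a metabolite absent from
#'     the organism is filtered.}
#'   \item{confidence-order}{an irreducible disagreement resolved by
#'     source rank.}
#'   \item{subset-rule}{non-reference claims contained in the reference
#'     set; not a conflict.}
#' }
#'
#' @param ref reference [metabolic_model()].
#' @param tg target genome from [make_target_genome()].
#' @param conflict_spec archetypes to plant (default all five).
#' @param n_novel number of novel (database-matching) ECs.
#' @param seed RNG seed.
#' @return list with `tables` (named list of data.frames gene/ec, the
#'   RAST one also carrying `designation`), `reference_claims` (the
#'   reference-model source, on target gene ids), `transfer_table`,
#'   `exclusions`, `generic_ecs`, `novel_ecs`, `loop_ecs`, and
#'   `expected` (per archetype gene: resolved ECs and basis).
#' @export
make_annotation_tables <- function(ref, tg,
                                   conflict_spec = c("ec-transfer",
                                                     "evidence-exclusion",
                                                     "generic-metabolite",
                                                     "confidence-order",
                                                     "subset-rule"),
                                   n_novel = 4, seed = 1) {
  with_seed(seed, {
    strict <- tg$truth$strict
    map <- stats::setNames(strict$target, strict$ref)
    # ECs a target gene inherits through its reference ortholog
    ec_by_gene <- list()
    for (r in ref$reactions) {
      if (is.null(r$gpr) || length(r$ec) == 0) next
      for (g in intersect(gpr_genes(r$gpr), names(map))) {
        t <- map[[g]]
        ec_by_gene[[t]] <- union(ec_by_gene[[t]], r$ec)
      }
    }
    uni <- list(); ncbi <- list(); rast <- list()
    claim <- function(store, gene, ecs, designation = NA_character_) {
      store[[length(store) + 1L]] <- data.frame(
        gene = gene, ec = paste(ecs, collapse = ";"),
        designation = designation, stringsAsFactors = FALSE)
      store
    }
    for (t in names(ec_by_gene)) {
      ecs <- ec_by_gene[[t]]
      if (stats::runif(1) < 0.85) uni <- claim(uni, t, ecs)
      if (stats::runif(1) < 0.6) ncbi <- claim(ncbi, t, ecs)
      if (stats::runif(1) < 0.85) rast <- claim(rast, t, ecs, paste("enzyme", ecs[1]))
    }
    # novel ECs beyond the reference chemistry live on genes without
    # reference orthologs, so no competing reference claim exists;
    # uniprot + rast agree, two isozyme genes share each EC
    novel_ecs <- sprintf("1.14.13.%d", 200 + seq_len(n_novel))
    for (k in seq_len(n_novel)) {
      gs <- sprintf("tnov_%d_%d", k, 1:2)
      des <- sprintf("novel oxidoreductase %d", k)
      for (g in gs) {
        uni <- claim(uni, g, novel_ecs[k])
        rast <- claim(rast, g, novel_ecs[k], des)
      }
    }
    # loop-reaction ECs: claimed by RAST alone on ortholog-less genes,
    # the single-source situation that lets spurious chemistry through
    loop_ecs <- sprintf("5.99.1.%d", 1:3)
    for (k in 1:3) {
      rast <- claim(rast, sprintf("tloop_%d", k), loop_ecs[k],
                    sprintf("putative isomerase L%d", k))
    }
    transfer_table <- data.frame(old = "2.5.1.8", new = "2.5.1.75",
                                 stringsAsFactors = FALSE)
    exclusions <- data.frame(ec = "1.1.1.26",
                             reason = "protein family restricted to hyperthermophilic archaea",
                             stringsAsFactors = FALSE)
    generic_ecs <- "1.3.5.1"  # acts on a quinone absent from the organism
    ref_claims <- list()
    expected <- list()
    if ("ec-transfer" %in% conflict_spec) {
      uni <- claim(uni, "tconf_transfer", "2.5.1.75")
      ncbi <- claim(ncbi, "tconf_transfer", "2.5.1.75")
      rast <- claim(rast, "tconf_transfer", "2.5.1.8")
      expected$tconf_transfer <- list(resolved = "2.5.1.75",
                                      basis = "agreement_after_transfer")
    }
    if ("evidence-exclusion" %in% conflict_spec) {
      ref_claims <- claim(ref_claims, "tconf_evidence", "1.1.1.29")
      rast <- claim(rast, "tconf_evidence", c("1.1.1.26", "1.1.1.81"))
      expected$tconf_evidence <- list(resolved = "1.1.1.29",
                                      basis = "confidence_order")
    }
    if ("generic-metabolite" %in% conflict_spec) {
      ref_claims <- claim(ref_claims, "tconf_generic", "1.3.99.1")
      rast <- claim(rast, "tconf_generic", "1.3.99.1")
      ncbi <- claim(ncbi, "tconf_generic", "1.3.5.1")
      expected$tconf_generic <- list(resolved = "1.3.99.1", basis = "agreement")
    }
    if ("confidence-order" %in% conflict_spec) {
      uni <- claim(uni, "tconf_order", "2.6.1.1")
      rast <- claim(rast, "tconf_order", "2.6.1.2")
      expected$tconf_order <- list(resolved = "2.6.1.1",
                                   basis = "confidence_order")
    }
    if ("subset-rule" %in% conflict_spec) {
      ref_claims <- claim(ref_claims, "tconf_subset", c("3.1.3.11", "3.1.3.37"))
      rast <- claim(rast, "tconf_subset", "3.1.3.11")
      expected$tconf_subset <- list(resolved = c("3.1.3.11", "3.1.3.37"),
                                    basis = "subset_rule")
    }
    bind <- function(x) {
      if (length(x) == 0) {
        return(data.frame(gene = character(0), ec = character(0),
                          designation = character(0), stringsAsFactors = FALSE))
      }
      do.call(rbind, x)
    }
    list(tables = list(uniprot = bind(uni)[c("gene", "ec")],
                       ncbi = bind(ncbi)[c("gene", "ec")],
                       rast = bind(rast)),
         reference_claims = bind(ref_claims)[c("gene", "ec")],
         transfer_table = transfer_table, exclusions = exclusions,
         generic_ecs = generic_ecs, novel_ecs = novel_ecs,
         loop_ecs = loop_ecs, expected = expected)
  })
}

#' Generate a universal (SEED-like) reaction database
#'
#' Balanced reactions keyed by EC: one entry per novel EC extending the
#' reference chemistry, one unbalanced decoy entry (excluded by the
#' balanced-only rule), optionally a planted three-reaction
#' thermodynamically infeasible loop (one member carrying a decisive
#' ΔG of +8 ± 2 kcal/mol) and a gapfill rescue reaction duplicating the
#' carbon-fixation step under a database id.
#'
#' @param ref reference [metabolic_model()].
#' @param novel_ecs ECs to give retrievable reactions (e.g. from
#'   [make_annotation_tables()]).
#' @param loop_ecs ECs for the planted loop (length 3) or `NULL` to skip.
#' @param rescue plant the rescue reaction?
#' @param seed RNG seed.
#' @return list with `db` (list of [reaction()]s carrying `balanced`
#'   attributes), `table` (tabular-dialect data.frame with a `balanced`
#'   column), `loop_ids`, `rescue_id`, `unbalanced_id`.
#' @export
make_seed_db <- function(ref, novel_ecs = character(0), loop_ecs = NULL,
                         rescue = TRUE, seed = 1) {
  with_seed(seed, {
    rows <- list()
    addu <- function(id, eq, ec, dG = round(stats::runif(1, -2, 2), 2),
                     dG_err = round(stats::runif(1, 0.5, 2), 2), balanced = 1) {
      rows[[length(rows) + 1L]] <<- data.frame(
        id = id, equation = eq, ec = paste(ec, collapse = ";"),
        dG = dG, dG_err = dG_err, balanced = balanced,
        stringsAsFactors = FALSE)
    }
    pool <- c("P1[c]", "P2[c]", "P3[c]", "P4[c]", "P5[c]")
    for (k in seq_along(novel_ecs)) {
      addu(sprintf("U%02d", k),
           sprintf("%s <=> q%02d[c]", sample(pool, 1), k), novel_ecs[k])
    }
    unbalanced_id <- NULL
    if (length(novel_ecs)) {
      unbalanced_id <- "UX_unbalanced"
      addu(unbalanced_id, sprintf("%s <=> qx[c]", sample(pool, 1)),
           novel_ecs[1], balanced = 0)
    }
    loop_ids <- character(0)
    if (!is.null(loop_ecs)) {
      stopifnot(length(loop_ecs) == 3)
      loop_ids <- c("LOOP1", "LOOP2", "LOOP3")
      addu("LOOP1", "yl1[c] <=> yl2[c]", loop_ecs[1], dG = 8, dG_err = 2)
      addu("LOOP2", "yl2[c] <=> yl3[c]", loop_ecs[2], dG = NA, dG_err = NA)
      addu("LOOP3", "yl3[c] <=> yl1[c]", loop_ecs[3], dG = NA, dG_err = NA)
    }
    rescue_id <- NULL
    if (rescue) {
      rescue_id <- "U_rescue"
      addu(rescue_id, "co2[c] + atp[c] => cfix[c]", character(0))
    }
    table <- do.call(rbind, rows)
    db <- model_from_tables("universal_db", table)$reactions
    for (k in seq_len(nrow(table))) {
      attr(db[[table$id[k]]], "balanced") <- table$balanced[k] == 1
    }
    list(db = db, table = table, loop_ids = loop_ids,
         rescue_id = rescue_id, unbalanced_id = unbalanced_id)
  })
}

#' Write a complete synthetic input bundle
#'
#' Generates reference model, BLAST tables, annotation tables, EC
#' transfer/exclusion/generic files, universal database, growth-condition
#' config and ground truth, and writes them under `dir` together with a
#' pipeline `config.yaml`. Regenerating with the same seed reproduces the
#' files byte for byte.
#'
#' @param dir output directory (created).
#' @param seed master RNG seed.
#' @param n_rxns,n_genes reference model size.
#' @param ortholog_fraction fraction of reference genes with strict
#'   orthologs.
#' @return list with `config` (path to config.yaml), `paths`, and
#'   `truth` (planted ground truth, also saved as `ground_truth.json`).
#' @export
make_fixture_bundle <- function(dir, seed = 1, n_rxns = 30, n_genes = 24,
                                ortholog_fraction = 0.7) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- make_reference_model(n_rxns, n_genes, seed = seed)
  tg <- make_target_genome(ref, ortholog_fraction, seed = seed + 1)
  ann <- make_annotation_tables(ref, tg, seed = seed + 2)
  db <- make_seed_db(ref, ann$novel_ecs, ann$loop_ecs, rescue = FALSE,
                     seed = seed + 3)
  p <- function(...) file.path(dir, ...)
  write_model(ref, p("reference"), format = "tabular")
  write_blast_tabular(tg$fwd, p("blast_fwd.tsv"))
  write_blast_tabular(tg$rev, p("blast_rev.tsv"))
  wt <- function(df, path) utils::write.table(df, path, sep = "\t", quote = FALSE,
                                              row.names = FALSE, na = "")
  for (src in names(ann$tables)) wt(ann$tables[[src]], p(paste0("annotations_", src, ".tsv")))
  wt(ann$reference_claims, p("annotations_reference_extra.tsv"))
  wt(ann$transfer_table, p("ec_transfer.tsv"))
  wt(ann$exclusions, p("ec_exclusions.tsv"))
  writeLines(ann$generic_ecs, p("generic_ecs.txt"))
  wt(db$table, p("universal_db.tsv"))
  config <- list(
    reference = "reference",
    blast = list(fwd = "blast_fwd.tsv", rev = "blast_rev.tsv"),
    annotations = list(uniprot = "annotations_uniprot.tsv",
                       ncbi = "annotations_ncbi.tsv",
                       rast = "annotations_rast.tsv"),
    reference_annotations_extra = "annotations_reference_extra.tsv",
    confidence_order = c("reference", "uniprot", "ncbi", "rast"),
    ec_transfer = "ec_transfer.tsv",
    exclusions = "ec_exclusions.tsv",
    generic_ecs = "generic_ecs.txt",
    universal_db = "universal_db.tsv",
    conditions = list(autotrophic = lapply(autotrophic_condition(), as.numeric),
                      heterotrophic = lapply(heterotrophic_condition(), as.numeric)),
    thresholds = list(evalue_strict = 1e-30, evalue_relaxed = 1e-10,
                      biomass_floor_frac = 0.01, dg_threshold = 4,
                      alt_slack = 2),
    output_dir = "out")
  yaml::write_yaml(config, p("config.yaml"))
  truth <- list(strict_orthologs = tg$truth$strict,
                relaxed_orthologs = tg$truth$relaxed,
                expected_transfers = expected_transfer_ids(ref, tg$truth$strict),
                loop_ids = db$loop_ids,
                novel_ecs = ann$novel_ecs,
                conflict_expected = ann$expected)
  jsonlite::write_json(truth, p("ground_truth.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  list(config = p("config.yaml"), dir = dir, truth = truth)
}

expected_transfer_ids <- function(ref, strict_truth) {
  present <- strict_truth$ref
  ids <- character(0)
  for (r in ref$reactions) {
    if (!is.null(r$gpr) && evaluate_gpr(r$gpr, present)) ids <- c(ids, r$id)
  }
  sort(ids)
}
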