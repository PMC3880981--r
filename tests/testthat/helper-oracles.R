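# Independent oracles and small constructors shared across tests.

# Boolean oracle for GPR strings: substitute gene tokens with literals and
# let R's own parser/evaluator do the work (independent of parse_gpr).
oracle_gpr_eval <- function(gpr_string, present, genes) {
  s <- gpr_string
  s <- gsub("\\bor\\b", "|", s, ignore.case = TRUE)
  s <- gsub("\\band\\b", "&", s, ignore.case = TRUE)
  for (g in genes) {
    s <- gsub(paste0("\\b", g, "\\b"), if (g %in% present) "TRUE" else "FALSE", s)
  }
  isTRUE(eval(parse(text = s)))
}

# Random GPR tree rendered as a fully parenthesised string.
random_gpr_tree_string <- function(genes, depth = 3) {
  if (depth == 0 || stats::runif(1) < 0.35) {
    return(sample(genes, 1))
  }
  op <- sample(c("and", "or"), 1)
  n <- sample(2:3, 1)
  kids <- vapply(seq_len(n), function(i) random_gpr_tree_string(genes, depth - 1), "")
  paste0("(", paste(kids, collapse = paste0(" ", op, " ")), ")")
}

# Independent element/charge bookkeeping for balance checks.
oracle_net_elements <- function(stoich, formulas, charges) {
  net <- list()
  for (m in names(stoich)) {
    f <- formulas[[m]]
    toks <- regmatches(f, gregexpr("[A-Z][a-z]?[0-9]*", f))[[1]]
    for (tk in toks) {
      el <- sub("[0-9]+$", "", tk)
      n <- sub("^[A-Z][a-z]?", "", tk)
      n <- if (nzchar(n)) as.numeric(n) else 1
      net[[el]] <- (if (is.null(net[[el]])) 0 else net[[el]]) + stoich[[m]] * n
    }
  }
  list(elements = Filter(function(v) abs(v) > 1e-9, net),
       charge = sum(stoich * unlist(charges[names(stoich)])))
}

# A tiny chain model: EX_A (uptake <= 10) -> transport -> conversion -> drain.
chain_model <- function() {
  metabolic_model(
    "chain",
    do.call(rbind, lapply(c("A[e]", "A[c]", "B[c]"), metabolite)),
    list(reaction("EX_A", "A[e] <=>", lb = -10),
         reaction("T_A", "A[e] => A[c]"),
         reaction("AB", "A[c] => B[c]"),
         reaction("BIO", "B[c] =>")),
    biomass = "BIO")
}

# A closed 3-cycle plus an exchange-fed appendix, loop members tagged with
# the given provenance/sources.
loop_model <- function(prov = "seed_retrieval", sources = list(character(0),
                                                               character(0),
                                                               character(0)),
                       dG = c(NA, NA, NA), dG_err = c(NA, NA, NA)) {
  mets <- do.call(rbind, lapply(c("x[c]", "y[c]", "z[c]", "n[e]", "n[c]"),
                                metabolite))
  mk <- function(id, eq, k) {
    reaction(id, eq, provenance = prov, sources = sources[[k]],
             dG = dG[k], dG_err = dG_err[k])
  }
  metabolic_model(
    "loop",
    mets,
    list(mk("L1", "x[c] <=> y[c]", 1),
         mk("L2", "y[c] <=> z[c]", 2),
         mk("L3", "z[c] <=> x[c]", 3),
         reaction("EX_n", "n[e] <=>", lb = -10),
         reaction("T_n", "n[e] => n[c]"),
         reaction("SINK", "n[c] =>")),
    biomass = "SINK")
}

# Gapfill fixture with known structure: a linear chain with k steps removed
# into the candidate pool, one single-reaction bypass for the first removed
# step, an independent two-step alternative route, and inert decoys.
# Everything needed for brute-force verification is returned.
make_gapfill_fixture <- function(seed, n_decoys = 5, remove = 1) {
  set.seed(seed)
  rxns <- list(
    reaction("EX_S", "S[e] <=>", lb = -10),
    reaction("T_S", "S[e] => S[c]"),
    reaction("C1", "S[c] => M1[c]"),
    reaction("C2", "M1[c] => M2[c]"),
    reaction("C3", "M2[c] => M3[c]"),
    reaction("BIO", "M3[c] =>"))
  names(rxns) <- vapply(rxns, `[[`, "", "id")
  removable <- c("C1", "C2", "C3")
  gone <- sample(removable, remove)
  cand <- rxns[gone]
  draft_rxns <- rxns[setdiff(names(rxns), gone)]
  # single-reaction bypass equivalent to the first removed step
  alt <- reaction(paste0("ALT_", gone[1]),
                  stoich = rxns[[gone[1]]]$stoich, lb = 0, ub = 1000)
  cand[[alt$id]] <- alt
  # two-step detour around the first removed step
  halves <- list(
    reaction(paste0("DET1_", gone[1]),
             stoich = c(stats::setNames(-1, names(which(rxns[[gone[1]]]$stoich < 0))),
                        "DET[c]" = 1), lb = 0),
    reaction(paste0("DET2_", gone[1]),
             stoich = c("DET[c]" = -1,
                        stats::setNames(1, names(which(rxns[[gone[1]]]$stoich > 0)))),
             lb = 0))
  for (h in halves) cand[[h$id]] <- h
  for (k in seq_len(n_decoys)) {
    cand[[sprintf("DECOY%d", k)]] <- reaction(
      sprintf("DECOY%d", k),
      sprintf("d%d[c] <=> e%d[c]", k, k))
  }
  mets <- do.call(rbind, lapply(sort(unique(unlist(
    lapply(c(draft_rxns, cand), function(r) names(r$stoich))))), metabolite))
  draft <- metabolic_model("gapfix", mets[mets$id %in% unlist(
    lapply(draft_rxns, function(r) names(r$stoich))), , drop = FALSE],
    draft_rxns, biomass = "BIO")
  list(draft = draft, candidates = unname(cand), removed = gone)
}

# Brute-force gapfill oracle: one batched LP feasibility sweep over all
# candidate subsets up to `max_size`, then minimal-set filtering.
brute_force_gapfill <- function(problem, max_size) {
  model <- problem$model
  rids <- reaction_ids(model)
  A <- draftgsm:::model_matrix_spec(model)
  bb <- draftgsm:::model_bounds(model, problem$bounds)
  bio <- match(problem$biomass, rids)
  cand_idx <- match(problem$candidate_ids, rids)
  nc <- length(cand_idx)
  subsets <- list()
  for (sz in 0:max_size) {
    if (sz == 0) { subsets <- list(integer(0)); next }
    subsets <- c(subsets, utils::combn(nc, sz, simplify = FALSE))
  }
  probs <- lapply(subsets, function(S) {
    lb <- bb$lb; ub <- bb$ub
    off <- cand_idx[setdiff(seq_len(nc), S)]
    lb[off] <- 0; ub[off] <- 0
    cvec <- numeric(length(rids)); cvec[bio] <- -1
    list(c = cvec, A = A, row_lb = rep(0, A$m), row_ub = rep(0, A$m),
         lb = lb, ub = ub)
  })
  sols <- draftgsm:::solve_lp_batch(probs)
  feas <- vapply(sols, function(s) {
    s$status == "optimal" && -s$objective >= problem$floor - 1e-7
  }, logical(1))
  fsets <- subsets[feas]
  # minimal feasible sets: no feasible proper subset
  is_minimal <- vapply(seq_along(fsets), function(i) {
    !any(vapply(fsets, function(o) {
      length(o) < length(fsets[[i]]) && all(o %in% fsets[[i]])
    }, logical(1)))
  }, logical(1))
  lapply(fsets[is_minimal], function(S) sort(problem$candidate_ids[S]))
}

setequal_sets <- function(a, b) {
  key <- function(s) vapply(s, paste, "", collapse = "|")
  setequal(key(a), key(b))
}
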