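test_that("EC matching against the reference partitions exactly", {
  ref <- make_reference_model(seed = 61)
  # CBB carries 4.1.1.39; 9.9.9.9 matches nothing
  got <- match_ec_to_reference(c("4.1.1.39", "9.9.9.9"), ref)
  expect_true("CBB" %in% names(got$reactions))
  expect_equal(got$leftover, "9.9.9.9")
  # randomized mixed sets: partition is exact and disjoint
  ref_ecs <- unique(unlist(lapply(ref$reactions, `[[`, "ec")))
  set.seed(62)
  for (k in 1:10) {
    ask <- unique(c(sample(ref_ecs, 3), sprintf("8.8.8.%d", 1:2)))
    res <- match_ec_to_reference(ask, ref)
    matched_ecs <- intersect(ask, unlist(lapply(res$reactions, `[[`, "ec")))
    expect_setequal(c(matched_ecs, res$leftover), ask)
    expect_length(intersect(matched_ecs, res$leftover), 0)
  }
})

test_that("database retrieval honours the balanced-only rule", {
  ref <- make_reference_model(seed = 63)
  db <- make_seed_db(ref, novel_ecs = sprintf("1.14.13.%d", 201:203),
                     loop_ecs = NULL, rescue = FALSE, seed = 64)
  got <- retrieve_seed_reactions(c("1.14.13.201", "7.7.7.7"), db$db)
  expect_true("U01" %in% names(got$reactions))
  expect_false(db$unbalanced_id %in% names(got$reactions))
  expect_equal(got$unmatched, "7.7.7.7")
  expect_true(all(vapply(got$reactions, `[[`, "", "provenance") == "seed_retrieval"))
  # an EC carried by two balanced entries retrieves both
  db2 <- db$db
  extra <- db2[["U02"]]; extra$id <- "U02b"; extra$ec <- "1.14.13.201"
  attr(extra, "balanced") <- TRUE
  db2[["U02b"]] <- extra
  got2 <- retrieve_seed_reactions("1.14.13.201", db2)
  expect_setequal(names(got2$reactions), c("U01", "U02b"))
})

test_that("reactions touching generic metabolites are removed and logged", {
  mets <- rbind(metabolite("a[c]"), metabolite("acceptor[c]", is_generic = TRUE),
                metabolite("b[c]"))
  rxns <- list(reaction("ok", "a[c] => b[c]"),
               reaction("bad", "a[c] + acceptor[c] => b[c]"))
  out <- filter_generic(rxns, mets)
  expect_equal(vapply(out$kept, `[[`, "", "id"), "ok")
  expect_equal(vapply(out$removed, `[[`, "", "id"), "bad")
  empty <- filter_generic(list(), mets)
  expect_length(empty$kept, 0)
  expect_length(empty$removed, 0)
})

test_that("essential categories append without duplication", {
  ref <- make_reference_model(seed = 65)
  draft <- list()
  out <- append_essential(draft, ref)
  expect_true("PSII" %in% names(out))
  expect_true(all(vapply(out, `[[`, "", "provenance") == "essential_append"))
  # an already-transferred copy is not duplicated, and keeps its provenance
  psii <- ref$reactions[["PSII"]]; psii$provenance <- "reference_transfer"
  out2 <- append_essential(list(PSII = psii), ref)
  expect_equal(sum(names(out2) == "PSII"), 1)
  expect_equal(out2[["PSII"]]$provenance, "reference_transfer")
  # a same-stoichiometry database copy yields to the reference-derived one
  alias <- ref$reactions[["PSII"]]; alias$id <- "PSII_copy"
  alias$provenance <- "seed_retrieval"
  out3 <- append_essential(list(PSII_copy = alias), ref)
  expect_true("PSII" %in% names(out3))
  expect_false("PSII_copy" %in% names(out3))
  expect_identical(append_essential(draft, ref, categories = character(0)), draft)
})

test_that("draft assembly is order-independent under deduplication", {
  ref <- make_reference_model(seed = 66)
  tg <- make_target_genome(ref, 0.7, seed = 67)
  m <- ortholog_map(tg$fwd, tg$rev, 1e-30)
  transferred <- transfer_reactions(ref, m)
  db <- make_seed_db(ref, novel_ecs = "1.14.13.250", loop_ecs = NULL,
                     rescue = FALSE, seed = 68)
  seed_rxns <- retrieve_seed_reactions("1.14.13.250", db$db)$reactions
  parts <- list(transferred, seed_rxns,
                append_essential(list(), ref))
  assemble <- function(ord) {
    acc <- list()
    for (p in parts[ord]) acc <- c(acc, p[setdiff(names(p), names(acc))])
    dedupe_reactions(acc)
  }
  a <- assemble(1:3); b <- assemble(c(3, 1, 2)); c3 <- assemble(c(2, 3, 1))
  expect_setequal(names(a), names(b))
  expect_setequal(names(a), names(c3))
  key <- function(x) sort(vapply(x, function(r) canonical_stoich_key(r$stoich), ""))
  expect_identical(key(a), key(b))
  expect_true(all(vapply(a, function(r) nzchar(r$provenance), logical(1))))
})
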