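test_that("the reference generator is deterministic and biologically sane", {
  a <- make_reference_model(30, 24, seed = 17)
  b <- make_reference_model(30, 24, seed = 17)
  expect_identical(reactions_as_table(a), reactions_as_table(b))
  expect_false(identical(reactions_as_table(a),
                         reactions_as_table(make_reference_model(30, 24, seed = 18))))
  expect_silent(validate_model(a))
  expect_equal(n_reactions(a), 30)
  # biomass achievable under both nutrient regimes
  expect_gt(fba(a, bounds = autotrophic_condition())$objective, 0)
  expect_gt(fba(a, bounds = heterotrophic_condition())$objective, 0)
  # the essential categories are represented
  subs <- vapply(a$reactions, function(r) as.character(r$subsystem), "")
  expect_true(all(c("photosynthesis", "oxidative_phosphorylation",
                    "diffusion_transport", "exchange") %in% subs))
})

test_that("planted BLAST fixtures recover exactly the planted truth", {
  ref <- make_reference_model(seed = 19)
  for (frac in c(0, 0.5, 1)) {
    tg <- make_target_genome(ref, frac, seed = 20)
    m <- ortholog_map(tg$fwd, tg$rev, 1e-30)
    expect_equal(nrow(m), nrow(tg$truth$strict))
    expect_identical(sort(paste(m$ref, m$target)),
                     sort(paste(tg$truth$strict$ref, tg$truth$strict$target)))
  }
  # the decoy hits straddle both workflow cutoffs
  tg <- make_target_genome(ref, 0.5, relaxed_fraction = 0.3, seed = 23)
  if (nrow(tg$truth$relaxed)) {
    ev_rel <- tg$fwd$evalue[tg$fwd$query %in% tg$truth$relaxed$ref &
                              tg$fwd$subject %in% tg$truth$relaxed$target]
    expect_true(all(ev_rel > 1e-30 & ev_rel <= 1e-10))
  }
})

test_that("annotation fixtures resolve to their recorded expectations", {
  ref <- make_reference_model(seed = 25)
  tg <- make_target_genome(ref, 0.7, seed = 26)
  ann <- make_annotation_tables(ref, tg, seed = 27)
  asg <- collect_ec_assignments(
    c(list(reference = ann$reference_claims), lapply(ann$tables, `[`, c("gene", "ec"))),
    sources = c("reference", names(ann$tables)))
  res <- resolve_conflicts(asg, exclusions = ann$exclusions,
                           generic_ecs = ann$generic_ecs,
                           transfer_table = ec_transfer_table(ann$transfer_table))
  for (g in names(ann$expected)) {
    expect_setequal(res[[g]]$resolved, ann$expected[[g]]$resolved)
    expect_equal(res[[g]]$basis, ann$expected[[g]]$basis, info = g)
  }
})

test_that("the universal database fixture plants loop and rescue as promised", {
  ref <- make_reference_model(seed = 28)
  db <- make_seed_db(ref, novel_ecs = sprintf("1.14.13.%d", 201:204),
                     loop_ecs = sprintf("5.99.1.%d", 1:3), rescue = TRUE,
                     seed = 29)
  expect_setequal(db$loop_ids, c("LOOP1", "LOOP2", "LOOP3"))
  # assembling the loop into a model exposes exactly the planted members
  m <- ref
  for (id in db$loop_ids) {
    r <- db$db[[id]]; r$provenance <- "seed_retrieval"
    m <- add_reactions(m, list(r))
  }
  expect_setequal(find_cycle_reactions(m)$id, db$loop_ids)
  # the rescue reaction is the unique single-addition fix for a draft
  # missing carbon fixation under autotrophic bounds
  draft <- remove_reactions(ref, c("CBB", "GLY"))
  draft$biomass <- "BIOMASS"
  prob <- gapfill_problem(draft, list(db$db[[db$rescue_id]]),
                          bounds = autotrophic_condition())
  got <- gapfill_min_additions(prob)
  expect_equal(got$additions, db$rescue_id)
})

test_that("bundle regeneration is byte-identical per seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  b1 <- make_fixture_bundle(d1, seed = 5)
  b2 <- make_fixture_bundle(d2, seed = 5)
  files <- setdiff(list.files(d1, recursive = TRUE), "config.yaml")
  expect_true(length(files) > 8)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})
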