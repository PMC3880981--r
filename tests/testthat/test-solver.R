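test_that("FBA reproduces hand-computed LP optima", {
  m <- chain_model()
  # uptake bound of 10 limits the whole chain
  sol <- fba(m)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective, 10, tolerance = 1e-9)
  expect_equal(unname(sol$fluxes["EX_A"]), -10, tolerance = 1e-9)
  # steady state holds at the optimum
  S <- s_matrix(m)
  expect_lt(max(abs(S %*% sol$fluxes)), 1e-6)
  # all exchanges closed: nothing can flow
  sol0 <- fba(m, bounds = list(EX_A = c(0, 0)))
  expect_equal(sol0$objective, 0, tolerance = 1e-9)
  # forced uptake with a blocked chain is infeasible, reported not thrown
  m2 <- remove_reactions(m, "AB")
  m2$biomass <- "BIO"
  soli <- fba(m2, objective = "BIO", bounds = list(EX_A = c(-10, -5)))
  expect_equal(soli$status, "infeasible")
})

test_that("FBA optimum is invariant under reordering and reversible splitting", {
  m <- chain_model()
  base <- fba(m)$objective
  perm <- metabolic_model("perm", m$metabolites, rev(unname(m$reactions)),
                          biomass = "BIO")
  expect_equal(fba(perm)$objective, base, tolerance = 1e-9)
  # split the reversible exchange into irreversible halves
  split <- remove_reactions(m, "EX_A")
  split <- add_reactions(split, list(
    reaction("EX_A_out", "A[e] =>", lb = 0, ub = 1000),
    reaction("EX_A_in", stoich = c("A[e]" = 1), lb = 0, ub = 10)))
  split$biomass <- "BIO"
  expect_equal(fba(split, objective = "BIO")$objective, base, tolerance = 1e-9)
})

test_that("FVA matches hand LP ranges, brackets FBA, and exposes loops", {
  m <- chain_model()
  rng <- fva(m)
  expect_equal(rng$min[rng$id == "AB"], 0, tolerance = 1e-8)
  expect_equal(rng$max[rng$id == "AB"], 10, tolerance = 1e-8)
  sol <- fba(m)
  for (k in seq_len(nrow(rng))) {
    expect_gte(sol$fluxes[[rng$id[k]]], rng$min[k] - 1e-7)
    expect_lte(sol$fluxes[[rng$id[k]]], rng$max[k] + 1e-7)
  }
  # dead-end irreversible reaction is pinned to zero
  dead <- add_reactions(m, list(reaction("DEAD", "A[c] => D[c]", lb = 0)))
  dead$biomass <- "BIO"
  rngd <- fva(dead, reactions = "DEAD")
  expect_equal(c(rngd$min, rngd$max), c(0, 0), tolerance = 1e-8)
  # a closed 3-cycle spins to its numeric bounds in both directions
  lm <- loop_model()
  rngl <- fva(lm, reactions = c("L1", "L2", "L3"),
              bounds = list(EX_n = c(0, 0)))
  expect_true(all(rngl$min <= -1000 + 1e-6))
  expect_true(all(rngl$max >= 1000 - 1e-6))
})

test_that("gapfilling finds provably minimal addition sets", {
  fx <- make_gapfill_fixture(seed = 71, n_decoys = 5, remove = 1)
  prob <- gapfill_problem(fx$draft, fx$candidates)
  expect_true(prob$feasible)
  got <- gapfill_min_additions(prob)
  expect_equal(got$status, "optimal")
  expect_equal(got$n_additions, 1)
  expect_true(got$additions %in% c(fx$removed, paste0("ALT_", fx$removed)))
  # a draft that already grows needs nothing
  full <- gapfill_problem(chain_model(),
                          list(reaction("SPARE", "A[c] <=> B[c]")))
  expect_equal(gapfill_min_additions(full)$additions, character(0))
  # candidate ids must be disjoint from the draft
  expect_error(gapfill_problem(chain_model(), list(reaction("AB", "A[c] => B[c]"))),
               "already in draft")
})

test_that("infeasible gapfilling reports blocked biomass precursors", {
  draft <- metabolic_model(
    "stuck", rbind(metabolite("A[c]"), metabolite("B[c]")),
    list(reaction("BIO", "B[c] =>"), reaction("MAKE_A", stoich = c("A[c]" = 1),
                                              lb = 0, ub = 10)),
    biomass = "BIO")
  prob <- gapfill_problem(draft, list(reaction("NOPE", "A[c] => AX[c]")))
  got <- gapfill_min_additions(prob)
  expect_equal(got$status, "infeasible")
  expect_true("B[c]" %in% got$blocked_precursors)
})

test_that("alternative enumeration equals brute force on random fixtures", {
  for (seed in c(81, 82, 83)) {
    fx <- make_gapfill_fixture(seed = seed, n_decoys = 4,
                               remove = 1 + seed %% 2)
    prob <- gapfill_problem(fx$draft, fx$candidates)
    alts <- enumerate_alternatives(prob, slack = 2)
    expect_equal(alts$status, "optimal")
    oracle <- brute_force_gapfill(prob, max_size = alts$minimum + 2)
    oracle <- oracle[lengths(oracle) <= alts$minimum + 2]
    expect_true(setequal_sets(alts$sets, oracle), info = paste("seed", seed))
    # slack 0 returns exactly the global minima
    zero <- enumerate_alternatives(prob, slack = 0)
    expect_true(all(lengths(zero$sets) == alts$minimum))
    expect_true(setequal_sets(zero$sets, oracle[lengths(oracle) == alts$minimum]))
  }
})
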