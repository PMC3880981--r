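test_that("equation parsing handles coefficients, reversibility and drains", {
  eq <- parse_equation("2 A[c] + B[p] <=> C[c]")
  expect_equal(eq$stoich[["A[c]"]], -2)
  expect_equal(eq$stoich[["B[p]"]], -1)
  expect_equal(eq$stoich[["C[c]"]], 1)
  expect_true(eq$reversible)

  drain <- parse_equation("P1[c] + atp[c] =>")
  expect_setequal(names(drain$stoich), c("atp[c]", "P1[c]"))
  expect_false(drain$reversible)

  ex <- parse_equation("glc[e] <=>")
  expect_equal(ex$stoich, c("glc[e]" = -1))

  expect_error(parse_equation("A[c] B[c]"), "arrow")
})

test_that("model validation catches undeclared metabolites and bad bounds", {
  mets <- do.call(rbind, lapply(c("a[c]", "b[c]"), metabolite))
  expect_error(
    metabolic_model("m", mets, list(reaction("r1", "a[c] => ghost[c]"))),
    "undeclared metabolite")
  expect_error(reaction("r2", "a[c] => b[c]", lb = 5, ub = 1),
               "lower bound exceeds")
  expect_error(reaction("r3", stoich = c("a[c]" = 0)), "empty stoichiometry")
})

test_that("tabular write/read round-trips ids, stoichiometry, bounds and GPRs", {
  ref <- make_reference_model(28, 20, seed = 7)
  dir <- withr::local_tempdir()
  write_model(ref, dir, format = "tabular")
  back <- read_model(dir, format = "tabular")
  expect_setequal(reaction_ids(back), reaction_ids(ref))
  expect_setequal(metabolite_ids(back), metabolite_ids(ref))
  expect_equal(back$biomass, ref$biomass)
  for (id in reaction_ids(ref)) {
    a <- ref$reactions[[id]]; b <- back$reactions[[id]]
    expect_equal(sort(names(a$stoich)), sort(names(b$stoich)), info = id)
    expect_equal(a$stoich[sort(names(a$stoich))], b$stoich[sort(names(b$stoich))],
                 info = id)
    expect_equal(c(a$lb, a$ub), c(b$lb, b$ub), info = id)
    genes <- union(gpr_genes(a$gpr), gpr_genes(b$gpr))
    if (length(genes) == 0) {
      expect_true(is.null(a$gpr) == is.null(b$gpr), info = id)
    } else {
      for (k in 0:(2^length(genes) - 1)) {
        present <- genes[bitwAnd(k, 2^(seq_along(genes) - 1)) > 0]
        expect_identical(evaluate_gpr(a$gpr, present), evaluate_gpr(b$gpr, present),
                         info = id)
      }
    }
  }
})

test_that("duplicate detection is reversal-invariant, symmetric and transitive", {
  mets <- do.call(rbind, lapply(c("a[c]", "b[c]", "c[c]"), metabolite))
  m <- metabolic_model("dup", mets, list(
    reaction("f1", "a[c] + b[c] => c[c]"),
    reaction("f2", "a[c] + b[c] => c[c]"),
    reaction("f3", stoich = c("a[c]" = 1, "b[c]" = 1, "c[c]" = -1)),  # reversed
    reaction("g1", "a[c] => b[c]")))
  groups <- find_duplicate_reactions(m)
  expect_length(groups, 1)
  expect_setequal(groups[[1]], c("f1", "f2", "f3"))

  uniq <- metabolic_model("u", mets, list(reaction("r", "a[c] => b[c]"),
                                          reaction("s", "b[c] => c[c]")))
  expect_length(find_duplicate_reactions(uniq), 0)

  # canonical key invariant under reversal, for random stoichiometries
  set.seed(9)
  for (k in 1:25) {
    ids <- paste0("m", 1:4, "[c]")
    s <- stats::setNames(sample(c(-2, -1, 1, 2), 4, replace = TRUE), ids)
    expect_identical(canonical_stoich_key(s), canonical_stoich_key(-s))
  }
})

test_that("balance checking agrees with independent element counting", {
  mets <- rbind(
    metabolite("h2o[c]", formula = "H2O", charge = 0L),
    metabolite("atp[c]", formula = "C10H12N5O13P3", charge = -4L),
    metabolite("adp[c]", formula = "C10H12N5O10P2", charge = -3L),
    metabolite("pi[c]", formula = "HO4P", charge = -2L),
    metabolite("h[c]", formula = "H", charge = 1L),
    metabolite("myst[c]"))
  hyd <- reaction("ATPASE", "atp[c] + h2o[c] => adp[c] + pi[c] + h[c]")
  rep <- check_balance(hyd, mets)
  expect_equal(rep$status, "balanced")
  expect_length(rep$elements, 0)
  expect_equal(rep$charge, 0)

  # deliberately drop the proton: net H of -1
  broken <- reaction("BAD", "atp[c] + h2o[c] => adp[c] + pi[c]")
  rep2 <- check_balance(broken, mets)
  expect_equal(rep2$status, "imbalanced")
  expect_equal(unname(rep2$elements["H"]), -1)

  unk <- reaction("UNK", "myst[c] => h2o[c]")
  expect_equal(check_balance(unk, mets)$status, "unknown")

  # randomized balanced reactions: A + B -> AB with composite formula
  set.seed(11)
  for (k in 1:100) {
    fa <- sprintf("C%dH%dO%d", sample(1:9, 1), sample(1:12, 1), sample(1:6, 1))
    fb <- sprintf("C%dH%dN%d", sample(1:9, 1), sample(1:12, 1), sample(1:4, 1))
    ca <- sample(-2:2, 1); cb <- sample(-2:2, 1)
    pa <- parse_formula(fa); pb <- parse_formula(fb)
    comb <- tapply(c(pa, pb), c(names(pa), names(pb)), sum)
    fab <- paste0(names(comb), ifelse(comb > 1, comb, ""), collapse = "")
    tab <- rbind(metabolite("a[c]", formula = fa, charge = as.integer(ca)),
                 metabolite("b[c]", formula = fb, charge = as.integer(cb)),
                 metabolite("ab[c]", formula = fab, charge = as.integer(ca + cb)))
    rxn <- reaction("J", "a[c] + b[c] => ab[c]")
    got <- check_balance(rxn, tab)
    ora <- oracle_net_elements(rxn$stoich,
                               list("a[c]" = fa, "b[c]" = fb, "ab[c]" = fab),
                               list("a[c]" = ca, "b[c]" = cb, "ab[c]" = ca + cb))
    expect_equal(got$status, if (length(ora$elements) == 0 &&
                                 abs(ora$charge) < 1e-9) "balanced" else "imbalanced")
  }
})

test_that("exchange reactions are recognised by boundary stoichiometry", {
  ref <- make_reference_model(seed = 3)
  ex <- is_exchange(ref)
  expect_true(all(startsWith(names(which(ex)), "EX_")))
  expect_false(any(ex[c("PSII", "BIOMASS", "T_nh4")]))
})
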