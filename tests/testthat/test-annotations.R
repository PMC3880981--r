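test_that("only fully specified EC numbers are ingested", {
  tab <- data.frame(gene = c("g1", "g2", "g3"),
                    ec = c("2.5.1.8", "1.1.1.-", "1.1.1.1;2.-.-.-"),
                    stringsAsFactors = FALSE)
  w <- capture_warnings(got <- collect_ec_assignments(list(rast = tab)))
  expect_length(w, 2)  # one per gene with a wildcard EC
  expect_match(w, "non-specific", all = TRUE)
  expect_setequal(got$gene, c("g1", "g3"))
  expect_setequal(got$ec, c("2.5.1.8", "1.1.1.1"))
  empty <- collect_ec_assignments(list(rast = tab[0, ]))
  expect_equal(nrow(empty), 0)
  expect_error(collect_ec_assignments(list(tab)), "named")
})

test_that("EC transfer table closes transitively and rejects cycles", {
  tab <- data.frame(old = c("a.1.1.1", "b.1.1.1"), new = c("b.1.1.1", "c.1.1.1"))
  closed <- ec_transfer_table(tab)
  expect_equal(unname(closed["a.1.1.1"]), "c.1.1.1")
  expect_equal(unname(closed["b.1.1.1"]), "c.1.1.1")
  asg <- data.frame(gene = "g", source = "rast", ec = c("a.1.1.1", "z.9.9.9"))
  norm <- normalize_ecs(asg, closed)
  expect_setequal(norm$ec, c("c.1.1.1", "z.9.9.9"))
  # idempotent
  expect_equal(normalize_ecs(norm, closed), norm)
  cyc <- data.frame(old = c("a.1.1.1", "b.1.1.1"), new = c("b.1.1.1", "a.1.1.1"))
  expect_error(ec_transfer_table(cyc), "cycle")
})

worked_examples <- function() {
  asg <- rbind(
    # apparent mismatch dissolved by the EC transfer history
    data.frame(gene = "PCC7424_1895", source = c("uniprot", "ncbi", "rast"),
               ec = c("2.5.1.75", "2.5.1.75", "2.5.1.8")),
    # archaeal-family exclusion then confidence order
    data.frame(gene = "PCC7424_2477", source = c("reference", "rast", "rast"),
               ec = c("1.1.1.29", "1.1.1.26", "1.1.1.81")),
    # succinate dehydrogenase: the ubiquinone-specific claim is filtered
    # because ubiquinone does not occur in the organism
    data.frame(gene = "Cyan7425_1569", source = c("reference", "rast", "ncbi"),
               ec = c("1.3.99.1", "1.3.99.1", "1.3.5.1")))
  list(assignments = asg,
       transfer = ec_transfer_table(data.frame(old = "2.5.1.8", new = "2.5.1.75")),
       exclusions = data.frame(ec = "1.1.1.26",
                               reason = "family found in hyperthermophilic archaea"),
       generic = "1.3.5.1")
}

test_that("the three canonical conflict cases resolve as documented", {
  w <- worked_examples()
  res <- resolve_conflicts(w$assignments, exclusions = w$exclusions,
                           generic_ecs = w$generic, transfer_table = w$transfer)
  expect_equal(res[["PCC7424_1895"]]$resolved, "2.5.1.75")
  expect_false(res[["PCC7424_1895"]]$conflicting)
  expect_true("ec_transfer" %in% res[["PCC7424_1895"]]$steps)

  expect_equal(res[["PCC7424_2477"]]$resolved, "1.1.1.29")
  expect_equal(res[["PCC7424_2477"]]$basis, "confidence_order")
  expect_true(all(c("evidence_exclusion", "confidence_order") %in%
                    res[["PCC7424_2477"]]$steps))

  expect_equal(res[["Cyan7425_1569"]]$resolved, "1.3.99.1")
  expect_true("generic_metabolite" %in% res[["Cyan7425_1569"]]$steps)
})

test_that("subset rule, empty survivors and confidence order behave", {
  asg <- rbind(
    data.frame(gene = "gs", source = c("reference", "reference", "rast"),
               ec = c("1.1.1.1", "2.2.2.2", "1.1.1.1")),
    data.frame(gene = "go", source = c("uniprot", "rast"),
               ec = c("3.3.3.3", "4.4.4.4")),
    data.frame(gene = "gz", source = "rast", ec = "5.5.5.5"))
  res <- resolve_conflicts(asg, generic_ecs = "5.5.5.5")
  expect_setequal(res[["gs"]]$resolved, c("1.1.1.1", "2.2.2.2"))
  expect_equal(res[["gs"]]$basis, "subset_rule")
  expect_false(res[["gs"]]$conflicting)
  expect_equal(res[["go"]]$resolved, "3.3.3.3")
  expect_equal(res[["go"]]$basis, "confidence_order")
  # single-source gene whose claim is filtered: resolved empty, logged
  expect_message(
    res2 <- resolve_conflicts(asg[asg$gene == "gz", ], generic_ecs = "5.5.5.5"),
    "no EC claims survive")
  expect_length(res2[["gz"]]$resolved, 0)
})

test_that("resolution is deterministic and never emits excluded or generic ECs", {
  set.seed(51)
  srcs <- c("reference", "uniprot", "ncbi", "rast")
  pool <- sprintf("1.2.3.%d", 1:8)
  excl <- data.frame(ec = "1.2.3.1", reason = "test")
  gen <- "1.2.3.2"
  rows <- do.call(rbind, lapply(1:25, function(g) {
    n <- sample(2:5, 1)
    data.frame(gene = paste0("g", g), source = sample(srcs, n, replace = TRUE),
               ec = sample(pool, n, replace = TRUE), stringsAsFactors = FALSE)
  }))
  r1 <- resolve_conflicts(rows, exclusions = excl, generic_ecs = gen)
  r2 <- resolve_conflicts(rows, exclusions = excl, generic_ecs = gen)
  expect_identical(resolved_ecs(r1), resolved_ecs(r2))
  for (rec in r1) {
    expect_false(any(c("1.2.3.1", "1.2.3.2") %in% rec$resolved), info = rec$gene)
    expect_true(all(rec$resolved %in% unlist(rec$claims)), info = rec$gene)
  }
  # reordering confidence only moves genes resolved by confidence order
  r3 <- resolve_conflicts(rows, order = c("reference", "rast", "ncbi", "uniprot"),
                          exclusions = excl, generic_ecs = gen)
  for (g in names(r1)) {
    if (r1[[g]]$basis != "confidence_order") {
      expect_identical(r1[[g]]$resolved, r3[[g]]$resolved, info = g)
    }
  }
})
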