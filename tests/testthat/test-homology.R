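blast_row <- function(q, s, ev, bits = 100, pid = 45) {
  data.frame(query = q, subject = s, pct_identity = pid, length = 300L,
             mismatch = 0L, gapopen = 0L, qstart = 1L, qend = 300L,
             sstart = 1L, send = 300L, evalue = ev, bitscore = bits,
             stringsAsFactors = FALSE)
}

test_that("tabular BLAST parsing reads 12-column files and rejects others", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_blast_tabular(rbind(blast_row("q1", "s1", 1e-40),
                            blast_row("q2", "s2", 1e-30),
                            blast_row("q3", "s3", 2e-5)), path)
  hits <- parse_blast_tabular(path)
  expect_equal(nrow(hits), 3)
  expect_equal(hits$evalue[1], 1e-40)
  expect_equal(hits$query, c("q1", "q2", "q3"))

  writeLines(c("a\tb\tc"), path)
  expect_error(parse_blast_tabular(path), "row 1")

  writeLines(character(0), path)
  expect_equal(nrow(parse_blast_tabular(path)), 0)
})

test_that("best-hit selection applies the cutoff and deterministic tie-breaks", {
  hits <- rbind(blast_row("q", "s1", 1e-40, bits = 150),
                blast_row("q", "s2", 1e-35, bits = 200))
  expect_equal(unname(best_hits(hits, 1e-30)["q"]), "s1")

  # e-value tie: higher bitscore wins; bitscore tie: smaller id wins.
  # Verified against exhaustive ranking of every permutation of the rows.
  tied <- rbind(blast_row("q", "sB", 1e-40, bits = 200),
                blast_row("q", "sA", 1e-40, bits = 180),
                blast_row("q", "sC", 1e-40, bits = 200))
  perms <- list(1:3, c(2, 1, 3), c(3, 2, 1), c(2, 3, 1), c(3, 1, 2), c(1, 3, 2))
  for (p in perms) {
    expect_equal(unname(best_hits(tied[p, ], 1e-30)["q"]), "sB")
  }

  # hit above cutoff: query absent
  expect_false("q" %in% names(best_hits(blast_row("q", "s", 1e-20), 1e-30)))
  # self-hits excluded
  selfy <- rbind(blast_row("g", "g", 1e-80), blast_row("g", "s", 1e-40))
  expect_equal(unname(best_hits(selfy, 1e-30)["g"]), "s")
  # multiple HSPs collapse to the best row
  hsps <- rbind(blast_row("q", "s", 1e-20), blast_row("q", "s", 1e-45))
  expect_equal(unname(attr(best_hits(hsps, 1e-30), "evalue")["q"]), 1e-45)
})

test_that("mutual best hits form an injective matching", {
  fwd <- structure(c(a = "x"), evalue = c(a = 1e-40))
  rev <- structure(c(x = "a"), evalue = c(x = 1e-42))
  m <- bidirectional_best_hits(fwd, rev)
  expect_equal(nrow(m), 1)
  expect_equal(m$ref, "a")
  expect_equal(m$evalue, 1e-40)  # worst direction

  rev2 <- structure(c(x = "b"), evalue = c(x = 1e-42))
  expect_equal(nrow(bidirectional_best_hits(fwd, rev2)), 0)
})

test_that("planted orthologs are recovered exactly and cutoffs are monotone", {
  ref <- make_reference_model(30, 26, seed = 21)
  for (frac in c(0, 0.6, 1)) {
    tg <- make_target_genome(ref, frac, seed = 22)
    m <- ortholog_map(tg$fwd, tg$rev, 1e-30)
    expect_equal(m$ref, tg$truth$strict$ref)
    expect_equal(m$target, tg$truth$strict$target)
    expect_false(anyDuplicated(m$ref) > 0)
    expect_false(anyDuplicated(m$target) > 0)

    relaxed <- ortholog_map(tg$fwd, tg$rev, 1e-10)
    expect_true(all(paste(m$ref, m$target) %in%
                      paste(relaxed$ref, relaxed$target)))
    expect_setequal(relaxed$ref, c(tg$truth$strict$ref, tg$truth$relaxed$ref))
    # tightening beyond every planted e-value removes everything
    expect_equal(nrow(ortholog_map(tg$fwd, tg$rev, 1e-300)), 0)
  }
})
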