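#' Reaction-content overlap between two models
#'
#' Reactions are matched by identifier (the workflow keeps one shared
#' reference/database namespace); reactions whose ids differ are also
#' matched when their canonical stoichiometry (see
#' [canonical_stoich_key()]) is identical.
#'
#' @param m1,m2 [metabolic_model()]s.
#' @param by `"id"` (default: id union stoichiometric fallback) or
#'   `"stoichiometry"` (hash only).
#' @param internal_only drop exchange reactions before counting.
#' @return a `similarity_counts` list: `A` shared, `B` unique to `m1`,
#'   `C` unique to `m2`, plus the shared ids.
#' @export
shared_reactions <- function(m1, m2, by = c("id", "stoichiometry"),
                             internal_only = FALSE) {
  by <- match.arg(by)
  pick <- function(m) {
    ids <- reaction_ids(m)
    if (internal_only) ids <- ids[!is_exchange(m)[ids]]
    ids
  }
  ids1 <- pick(m1); ids2 <- pick(m2)
  if (by == "stoichiometry") {
    k1 <- vapply(m1$reactions[ids1], function(r) canonical_stoich_key(r$stoich), "")
    k2 <- vapply(m2$reactions[ids2], function(r) canonical_stoich_key(r$stoich), "")
    shared <- ids1[k1 %in% k2]
    A <- length(unique(k1[k1 %in% k2]))
    B <- length(unique(k1)) - A
    C <- length(unique(k2)) - A
  } else {
    shared <- intersect(ids1, ids2)
    only1 <- setdiff(ids1, ids2); only2 <- setdiff(ids2, ids1)
    k1 <- vapply(m1$reactions[only1], function(r) canonical_stoich_key(r$stoich), "")
    k2 <- vapply(m2$reactions[only2], function(r) canonical_stoich_key(r$stoich), "")
    extra <- only1[k1 %in% k2]
    shared <- c(shared, extra)
    A <- length(shared)
    B <- length(only1) - length(extra)
    C <- length(only2) - length(extra)
  }
  structure(list(A = A, B = B, C = C, shared = shared),
            class = "similarity_counts")
}

#' Reaction-content similarity
#'
#' `similarity = A^2 / ((A + B) (A + C))` where A is the number of shared
#' reactions and B, C the counts unique to each model -- the squared
#' Ochiai form: 1 for identical reaction sets, 0 for disjoint ones,
#' symmetric in the two models.
#'
#' @param counts a `similarity_counts` from [shared_reactions()], or a
#'   list with numeric `A`, `B`, `C`.
#' @return similarity in `[0, 1]`.
#' @export
similarity <- function(counts) {
  A <- counts$A; B <- counts$B; C <- counts$C
  stopifnot(A >= 0, B >= 0, C >= 0)
  if (A + B == 0 || A + C == 0) {
    stop("similarity undefined for an empty model (A+B or A+C is zero)")
  }
  A^2 / ((A + B) * (A + C))
}

#' @export
print.similarity_counts <- function(x, ...) {
  cat("<similarity_counts> shared A=", x$A, "  unique B=", x$B,
      "  C=", x$C, "  similarity=",
      format(tryCatch(similarity(x), error = function(e) NA)), "\n", sep = "")
  invisible(x)
}

#' Pairwise similarity matrix for a set of models
#'
#' @param models named list of [metabolic_model()]s (>= 2).
#' @param ... passed to [shared_reactions()].
#' @return symmetric numeric matrix with unit diagonal.
#' @export
similarity_matrix <- function(models, ...) {
  stopifnot(length(models) >= 2)
  nms <- names(models)
  if (is.null(nms)) nms <- vapply(models, `[[`, "", "id")
  n <- length(models)
  M <- diag(1, n)
  dimnames(M) <- list(nms, nms)
  for (a in seq_len(n - 1)) {
    for (b in seq((a + 1), n)) {
      s <- similarity(shared_reactions(models[[a]], models[[b]], ...))
      M[a, b] <- s
      M[b, a] <- s
    }
  }
  M
}
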