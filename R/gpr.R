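#' Gene-protein-reaction (GPR) Boolean expressions
#'
#' A GPR is a Boolean rule over gene identifiers stating which gene
#' combinations enable a reaction: `or` joins isozymes (any one suffices),
#' `and` joins subunits of a protein complex (all required). Expressions are
#' stored as trees; leaves are gene identifiers.
#'
#' The grammar is the COBRA convention: case-insensitive `and` / `or`
#' keywords, parentheses, gene tokens are any non-whitespace identifiers
#' other than the keywords, and `and` binds tighter than `or`, so
#' `a or b and c` parses as `a or (b and c)`.
#'
#' @param text a GPR string; `""`, `NA` and whitespace-only give `NULL`
#'   (the empty GPR, which never enables a reaction).
#' @return `parse_gpr()` returns a `gpr` tree or `NULL`; internal nodes are
#'   lists with `$op` (`"and"`/`"or"`) and `$args`, leaves have `$gene`.
#' @examples
#' g <- parse_gpr("(geneA and geneB) or geneC")
#' evaluate_gpr(g, "geneC")
#' gpr_genes(g)
#' @export
parse_gpr <- function(text) {
  if (is.null(text) || length(text) == 0 || is.na(text)) return(NULL)
  text <- trimws(text)
  if (!nzchar(text)) return(NULL)
  toks <- gpr_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  node <- gpr_parse_or(st)
  if (st$pos <= length(st$toks)) {
    stop("GPR parse error: unexpected token '", st$toks[st$pos], "' in: ", text)
  }
  node
}

gpr_tokenize <- function(text) {
  text <- gsub("([()])", " \\1 ", text)
  toks <- strsplit(text, "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

gpr_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_

gpr_parse_or <- function(st) {
  args <- list(gpr_parse_and(st))
  while (!is.na(tk <- gpr_peek(st)) && tolower(tk) == "or") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_and(st)))
  }
  if (length(args) == 1L) args[[1]] else gpr_node("or", args)
}

gpr_parse_and <- function(st) {
  args <- list(gpr_parse_atom(st))
  while (!is.na(tk <- gpr_peek(st)) && tolower(tk) == "and") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_atom(st)))
  }
  if (length(args) == 1L) args[[1]] else gpr_node("and", args)
}

gpr_parse_atom <- function(st) {
  tk <- gpr_peek(st)
  if (is.na(tk)) stop("GPR parse error: unexpected end of expression")
  st$pos <- st$pos + 1L
  if (tk == "(") {
    node <- gpr_parse_or(st)
    if (is.na(gpr_peek(st)) || gpr_peek(st) != ")") {
      stop("GPR parse error: missing closing parenthesis")
    }
    st$pos <- st$pos + 1L
    return(node)
  }
  if (tk == ")" || tolower(tk) %in% c("and", "or")) {
    stop("GPR parse error: unexpected token '", tk, "'")
  }
  gpr_leaf(tk)
}

gpr_node <- function(op, args) structure(list(op = op, args = args), class = "gpr")
gpr_leaf <- function(gene) structure(list(gene = gene), class = "gpr")

is_gpr_leaf <- function(x) !is.null(x$gene)

#' @rdname parse_gpr
#' @param gpr a `gpr` tree (or `NULL`).
#' @return `deparse_gpr()` returns a single string (`""` for `NULL`).
#' @export
deparse_gpr <- function(gpr) {
  if (is.null(gpr)) return("")
  if (is_gpr_leaf(gpr)) return(gpr$gene)
  parts <- vapply(gpr$args, function(a) {
    s <- deparse_gpr(a)
    # parenthesize any compound child so precedence survives re-parsing
    if (!is_gpr_leaf(a)) s <- paste0("(", s, ")")
    s
  }, character(1))
  paste(parts, collapse = paste0(" ", gpr$op, " "))
}

#' @rdname parse_gpr
#' @return `gpr_genes()` returns the sorted unique gene identifiers.
#' @export
gpr_genes <- function(gpr) {
  if (is.null(gpr)) return(character(0))
  if (is_gpr_leaf(gpr)) return(gpr$gene)
  sort(unique(unlist(lapply(gpr$args, gpr_genes))))
}

#' Evaluate a GPR under a set of present genes
#'
#' Standard Boolean evaluation: a leaf is true iff its gene is in `present`,
#' `and` nodes require all arguments, `or` nodes at least one. The empty GPR
#' (`NULL`) evaluates `FALSE`: a reaction with no gene rule can never be
#' justified by homology evidence alone.
#'
#' @param gpr a `gpr` tree or `NULL`.
#' @param present character vector of gene identifiers considered present.
#' @return logical scalar.
#' @export
evaluate_gpr <- function(gpr, present) {
  if (is.null(gpr)) return(FALSE)
  if (is_gpr_leaf(gpr)) return(gpr$gene %in% present)
  if (is.null(gpr$op) || !gpr$op %in% c("and", "or")) {
    stop("malformed GPR tree: node has no valid operator")
  }
  vals <- vapply(gpr$args, evaluate_gpr, logical(1), present = present)
  if (gpr$op == "and") all(vals) else any(vals)
}

#' @export
print.gpr <- function(x, ...) {
  cat("<gpr> ", deparse_gpr(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.gpr <- function(x, ...) deparse_gpr(x)
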