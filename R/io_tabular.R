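#' Read / write metabolic models
#'
#' `read_model()` and `write_model()` dispatch on `format`. The tabular
#' dialect is a directory holding `reactions.tsv` (columns `id`, `name`,
#' `equation`, `lb`, `ub`, `gpr`, `ec` (semicolon-separated), `subsystem`,
#' `dG`, `dG_err`, `provenance`, `sources` (semicolon-separated),
#' `biomass` 0/1) and `metabolites.tsv` (columns `id`, `name`,
#' `compartment`, `formula`, `charge`, `is_generic` 0/1). The flat layout
#' exists so SEED-like reaction databases and hand-written fixtures share
#' one format. SBML support covers Level 3 FBC (written) and Level 2/3
#' COBRA-style files (read); see [read_sbml()].
#'
#' @param path for tabular: a directory; for SBML: an `.xml`/`.sbml` file.
#' @param format `"tabular"` or `"sbml"`; guessed from `path` when missing
#'   (directories and `.tsv` prefixes are tabular).
#' @param id model id; defaults to the directory or file base name.
#' @return `read_model()` returns a validated [metabolic_model()].
#' @export
read_model <- function(path, format = NULL, id = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "tabular"
  }
  format <- match.arg(format, c("tabular", "sbml"))
  switch(format,
         tabular = read_model_tabular(path, id = id),
         sbml = read_sbml(path))
}

#' @rdname read_model
#' @param model a [metabolic_model()].
#' @return `write_model()` returns `path` invisibly.
#' @export
write_model <- function(model, path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "tabular"
  }
  format <- match.arg(format, c("tabular", "sbml"))
  switch(format,
         tabular = write_model_tabular(model, path),
         sbml = write_sbml(model, path))
  invisible(path)
}

read_model_tabular <- function(path, id = NULL) {
  rfile <- file.path(path, "reactions.tsv")
  mfile <- file.path(path, "metabolites.tsv")
  if (!file.exists(rfile)) stop("not a tabular model directory (no reactions.tsv): ", path)
  rtab <- read_tsv(rfile)
  mtab <- if (file.exists(mfile)) read_tsv(mfile) else NULL
  if (is.null(id)) id <- basename(normalizePath(path, mustWork = FALSE))
  model_from_tables(id, rtab, mtab)
}

#' Build a model from the tabular dialect's data.frames
#'
#' @param id model id.
#' @param rtab reaction table (see [read_model()] for columns).
#' @param mtab metabolite table, or `NULL` to infer metabolites from the
#'   equations (unknown formula/charge, non-generic).
#' @return a validated [metabolic_model()].
#' @export
model_from_tables <- function(id, rtab, mtab = NULL) {
  need <- c("id", "equation")
  miss <- setdiff(need, names(rtab))
  if (length(miss)) stop("reaction table lacks column(s): ", paste(miss, collapse = ", "))
  col <- function(nm, default) if (nm %in% names(rtab)) rtab[[nm]] else rep(default, nrow(rtab))
  rxns <- vector("list", nrow(rtab))
  for (k in seq_len(nrow(rtab))) {
    eq <- tryCatch(parse_equation(rtab$equation[k]),
                   error = function(e) stop("reaction table row ", k, " (",
                                            rtab$id[k], "): ", conditionMessage(e)))
    lb <- col("lb", NA_real_)[k]; ub <- col("ub", NA_real_)[k]
    if (is.na(lb)) lb <- if (eq$reversible) -1000 else 0
    if (is.na(ub)) ub <- 1000
    rxns[[k]] <- reaction(
      id = rtab$id[k], stoich = eq$stoich, lb = lb, ub = ub,
      gpr = parse_gpr(as.character(col("gpr", "")[k])),
      ec = split_field(col("ec", "")[k]),
      provenance = one_or(col("provenance", "reference")[k], "reference"),
      sources = split_field(col("sources", "")[k]),
      dG = as.numeric(col("dG", NA_real_)[k]),
      dG_err = as.numeric(col("dG_err", NA_real_)[k]),
      subsystem = one_or(col("subsystem", NA_character_)[k], NA_character_),
      name = one_or(col("name", rtab$id[k])[k], rtab$id[k]))
  }
  met_ids <- sort(unique(unlist(lapply(rxns, function(r) names(r$stoich)))))
  if (is.null(mtab)) {
    mtab <- do.call(rbind, lapply(met_ids, metabolite))
  } else {
    mneed <- setdiff(c("id", "compartment"), names(mtab))
    if (length(mneed)) stop("metabolite table lacks column(s): ",
                            paste(mneed, collapse = ", "))
    mtab <- data.frame(
      id = mtab$id,
      name = if ("name" %in% names(mtab)) mtab$name else mtab$id,
      compartment = mtab$compartment,
      formula = as.character(if ("formula" %in% names(mtab)) mtab$formula else NA),
      charge = as.integer(if ("charge" %in% names(mtab)) mtab$charge else NA),
      is_generic = as.logical(if ("is_generic" %in% names(mtab)) mtab$is_generic else FALSE),
      stringsAsFactors = FALSE)
  }
  biomass <- character(0)
  if ("biomass" %in% names(rtab)) biomass <- rtab$id[as.logical(rtab$biomass) %in% TRUE]
  metabolic_model(id, mtab, rxns, biomass = biomass)
}

write_model_tabular <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  rtab <- reactions_as_table(model)
  mtab <- model$metabolites
  mtab$is_generic <- as.integer(mtab$is_generic)
  utils::write.table(rtab, file.path(path, "reactions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(mtab, file.path(path, "metabolites.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Flatten a model's reactions to the tabular dialect
#' @param model a [metabolic_model()].
#' @return data.frame, one row per reaction.
#' @export
reactions_as_table <- function(model) {
  rxns <- model$reactions
  data.frame(
    id = vapply(rxns, `[[`, "", "id"),
    name = vapply(rxns, `[[`, "", "name"),
    equation = vapply(rxns, format_equation, ""),
    lb = vapply(rxns, `[[`, 0, "lb"),
    ub = vapply(rxns, `[[`, 0, "ub"),
    gpr = vapply(rxns, function(r) deparse_gpr(r$gpr), ""),
    ec = vapply(rxns, function(r) paste(r$ec, collapse = ";"), ""),
    subsystem = vapply(rxns, function(r) as.character(r$subsystem), ""),
    dG = vapply(rxns, `[[`, 0, "dG"),
    dG_err = vapply(rxns, `[[`, 0, "dG_err"),
    provenance = vapply(rxns, `[[`, "", "provenance"),
    sources = vapply(rxns, function(r) paste(r$sources, collapse = ";"), ""),
    biomass = as.integer(names(rxns) %in% model$biomass),
    stringsAsFactors = FALSE, row.names = NULL)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    quote = "", comment.char = "", check.names = TRUE,
                    na.strings = c("NA", ""))
}

split_field <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  trimws(strsplit(as.character(x), ";")[[1]])
}

one_or <- function(x, default) {
  x <- as.character(x)
  if (length(x) == 0 || is.na(x) || !nzchar(x)) default else x
}
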