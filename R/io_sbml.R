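#' SBML input and output
#'
#' Models are written as SBML Level 3 Version 1 with the FBC version 2
#' extension: species carry `chemicalFormula`/`charge`, flux bounds are
#' shared `Parameter`s referenced via `fbc:lowerFluxBound` /
#' `fbc:upperFluxBound`, GPRs are `geneProductAssociation` trees, and the
#' biomass objective is the active FBC objective. The reader accepts both
#' these Level 3 FBC files and Level 2 COBRA-style exports (bounds in
#' `kineticLaw` parameters `LOWER_BOUND`/`UPPER_BOUND`, GPRs in
#' `GENE_ASSOCIATION` notes).
#'
#' Identifiers are mangled to SBML SIds the COBRA way: metabolite
#' `atp[c]` becomes species `M_atp_c` in compartment `c`, reaction ids are
#' prefixed `R_`, gene products are prefixed `G_` with the verbatim gene id
#' kept in `fbc:label`. The reader reverses the mangling using the
#' compartment attribute, so ids containing only word characters and the
#' compartment suffix round-trip exactly.
#'
#' @param path SBML file path.
#' @return `read_sbml()`: a validated [metabolic_model()].
#' @export
read_sbml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- xml2::read_xml(path)
  model_node <- xml_first(doc, "model")
  if (is.null(model_node)) stop("SBML parse error: no <model> element in ", path)
  mid <- attr_any(model_node, "id")
  if (is.na(mid)) mid <- tools::file_path_sans_ext(basename(path))

  comp_nodes <- xml_all(model_node, "compartment")
  comps <- vapply(comp_nodes, attr_any, "", "id")

  sp_nodes <- xml_all(model_node, "species")
  sp_id <- vapply(sp_nodes, attr_any, "", "id")
  sp_comp <- vapply(sp_nodes, attr_any, "", "compartment")
  sp_boundary <- vapply(sp_nodes, attr_any, "", "boundaryCondition") %in% "true"
  met_id <- unmangle_species(sp_id, sp_comp)
  mtab <- data.frame(
    id = met_id,
    name = ifelse(is.na(vapply(sp_nodes, attr_any, "", "name")), met_id,
                  vapply(sp_nodes, attr_any, "", "name")),
    compartment = sp_comp,
    formula = vapply(sp_nodes, attr_any, "", "chemicalFormula", "fbc:chemicalFormula"),
    charge = suppressWarnings(as.integer(
      vapply(sp_nodes, attr_any, "", "charge", "fbc:charge"))),
    is_generic = vapply(sp_nodes, attr_any, "", "is_generic") %in% "true",
    stringsAsFactors = FALSE)
  sp_lookup <- stats::setNames(met_id, sp_id)
  keep <- !sp_boundary
  mtab <- mtab[keep, , drop = FALSE]

  gp_nodes <- xml_all(model_node, "geneProduct")
  gp_label <- stats::setNames(
    vapply(gp_nodes, function(n) {
      lb <- attr_any(n, "label", "fbc:label")
      if (is.na(lb)) attr_any(n, "id", "fbc:id") else lb
    }, ""),
    vapply(gp_nodes, attr_any, "", "id", "fbc:id"))

  params <- xml_all(model_node, "parameter")
  par_val <- stats::setNames(
    suppressWarnings(as.numeric(vapply(params, attr_any, "", "value"))),
    vapply(params, attr_any, "", "id"))

  rxns <- list()
  for (rn in xml_all(model_node, "reaction")) {
    rid_raw <- attr_any(rn, "id")
    rid <- sub("^R_", "", rid_raw)
    stoich <- numeric(0)
    for (side in c("listOfReactants", "listOfProducts")) {
      sgn <- if (side == "listOfReactants") -1 else 1
      holder <- xml_first(rn, side)
      if (is.null(holder)) next
      for (sr in xml_all(holder, "speciesReference")) {
        sp <- attr_any(sr, "species")
        coef <- attr_any(sr, "stoichiometry")
        coef <- if (is.na(coef)) 1 else as.numeric(coef)
        target <- sp_lookup[[sp]]
        if (sp %in% sp_id[sp_boundary]) next  # boundary species: drop (exchange)
        stoich[target] <- (if (target %in% names(stoich)) stoich[[target]] else 0) +
          sgn * coef
      }
    }
    stoich <- stoich[stoich != 0]
    if (length(stoich) == 0) next
    rev_attr <- attr_any(rn, "reversible") %in% c("true", NA)
    bl <- sbml_bounds(rn, par_val, rev_attr)
    gpr <- sbml_gpr(rn, gp_label)
    notes_node <- xml_first(rn, "notes")
    notes <- if (is.null(notes_node)) "" else xml2::xml_text(notes_node)
    ec <- character(0)
    if (nzchar(notes)) {
      ecm <- regmatches(notes, regexpr("EC Number: *([0-9.; -]+)", notes))
      if (length(ecm)) ec <- split_field(gsub(" ", "", sub("EC Number: *", "", ecm)))
    }
    rxns[[rid]] <- reaction(id = rid, stoich = stoich, lb = bl[1], ub = bl[2],
                            gpr = gpr, ec = ec,
                            name = one_or(attr_any(rn, "name"), rid))
  }

  biomass <- character(0)
  for (fo in xml_all(model_node, "fluxObjective")) {
    biomass <- c(biomass, sub("^R_", "", attr_any(fo, "reaction", "fbc:reaction")))
  }
  if (length(comps) == 0) comps <- sort(unique(mtab$compartment))
  metabolic_model(mid, mtab, rxns, biomass = intersect(biomass, names(rxns)),
                  compartments = comps)
}

#' @rdname read_sbml
#' @param model a [metabolic_model()].
#' @return `write_sbml()`: `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  sbml_ns <- "http://www.sbml.org/sbml/level3/version1/core"
  fbc_ns <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub('"', "&quot;", x, fixed = TRUE)
  }
  num <- function(x) sprintf("%.12g", x)
  out <- c(sprintf('<?xml version="1.0" encoding="UTF-8"?>'),
           sprintf(paste0('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" ',
                          'fbc:required="false">'), sbml_ns, fbc_ns),
           sprintf('  <model id="%s" fbc:strict="false">', esc(sanitize_sid(model$id))))
  out <- c(out, "    <listOfCompartments>")
  for (cc in model$compartments) {
    nm <- if (cc %in% names(COMPARTMENT_CODES)) COMPARTMENT_CODES[[cc]] else cc
    out <- c(out, sprintf('      <compartment id="%s" name="%s" constant="true"/>',
                          esc(cc), esc(nm)))
  }
  out <- c(out, "    </listOfCompartments>", "    <listOfSpecies>")
  for (k in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[k, ]
    extra <- ""
    if (!is.na(m$formula)) extra <- paste0(extra, sprintf(' fbc:chemicalFormula="%s"', esc(m$formula)))
    if (!is.na(m$charge)) extra <- paste0(extra, sprintf(' fbc:charge="%d"', m$charge))
    if (isTRUE(m$is_generic)) extra <- paste0(extra, ' is_generic="true"')
    out <- c(out, sprintf(paste0('      <species id="%s" name="%s" compartment="%s" ',
                                 'hasOnlySubstanceUnits="false" boundaryCondition="false" ',
                                 'constant="false"%s/>'),
                          mangle_species(m$id, m$compartment), esc(m$name),
                          esc(m$compartment), extra))
  }
  out <- c(out, "    </listOfSpecies>")
  bounds <- sort(unique(unlist(lapply(model$reactions, function(r) c(r$lb, r$ub)))))
  bid <- stats::setNames(paste0("B_", seq_along(bounds)), num(bounds))
  out <- c(out, "    <listOfParameters>",
           sprintf('      <parameter id="%s" value="%s" constant="true"/>',
                   bid, names(bid)),
           "    </listOfParameters>")
  genes <- model_genes(model)
  if (length(genes)) {
    out <- c(out, "    <fbc:listOfGeneProducts>",
             sprintf('      <fbc:geneProduct fbc:id="%s" fbc:label="%s"/>',
                     paste0("G_", sanitize_sid(genes)), esc(genes)),
             "    </fbc:listOfGeneProducts>")
  }
  out <- c(out, "    <listOfReactions>")
  for (r in model$reactions) {
    out <- c(out, sprintf(paste0('      <reaction id="%s" name="%s" reversible="%s" ',
                                 'fast="false" fbc:lowerFluxBound="%s" ',
                                 'fbc:upperFluxBound="%s">'),
                          paste0("R_", sanitize_sid(r$id)), esc(r$name),
                          if (r$lb < 0) "true" else "false",
                          bid[[num(r$lb)]], bid[[num(r$ub)]]))
    if (length(r$ec)) {
      out <- c(out, "        <notes>",
               sprintf('          <body xmlns="http://www.w3.org/1999/xhtml"><p>EC Number: %s</p></body>',
                       esc(paste(r$ec, collapse = ";"))),
               "        </notes>")
    }
    subs <- r$stoich[r$stoich < 0]; prods <- r$stoich[r$stoich > 0]
    comp_by_id <- stats::setNames(model$metabolites$compartment, model$metabolites$id)
    if (length(subs)) {
      out <- c(out, "        <listOfReactants>",
               sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                       mangle_species(names(subs), comp_by_id[names(subs)]), num(-subs)),
               "        </listOfReactants>")
    }
    if (length(prods)) {
      out <- c(out, "        <listOfProducts>",
               sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                       mangle_species(names(prods), comp_by_id[names(prods)]), num(prods)),
               "        </listOfProducts>")
    }
    if (!is.null(r$gpr)) {
      out <- c(out, "        <fbc:geneProductAssociation>",
               gpr_to_fbc(r$gpr, indent = "          "),
               "        </fbc:geneProductAssociation>")
    }
    out <- c(out, "      </reaction>")
  }
  out <- c(out, "    </listOfReactions>")
  if (length(model$biomass)) {
    out <- c(out,
             '    <fbc:listOfObjectives fbc:activeObjective="obj">',
             '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
             "        <fbc:listOfFluxObjectives>",
             sprintf('          <fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="1"/>',
                     paste0("R_", sanitize_sid(model$biomass))),
             "        </fbc:listOfFluxObjectives>",
             "      </fbc:objective>",
             "    </fbc:listOfObjectives>")
  }
  out <- c(out, "  </model>", "</sbml>")
  writeLines(out, path)
  invisible(path)
}

gpr_to_fbc <- function(gpr, indent) {
  if (is_gpr_leaf(gpr)) {
    return(sprintf('%s<fbc:geneProductRef fbc:geneProduct="G_%s"/>',
                   indent, sanitize_sid(gpr$gene)))
  }
  tag <- if (gpr$op == "and") "fbc:and" else "fbc:or"
  c(sprintf("%s<%s>", indent, tag),
    unlist(lapply(gpr$args, gpr_to_fbc, indent = paste0(indent, "  "))),
    sprintf("%s</%s>", indent, tag))
}

sanitize_sid <- function(x) {
  x <- gsub("\\[([A-Za-z]+)\\]$", "_\\1", x)
  gsub("[^A-Za-z0-9_]", "_", x)
}

mangle_species <- function(id, compartment) {
  base <- sub("\\[[A-Za-z]+\\]$", "", id)
  paste0("M_", gsub("[^A-Za-z0-9_]", "_", base), "_", compartment)
}

unmangle_species <- function(sid, compartment) {
  base <- sub("^M_", "", sid)
  suff <- paste0("_", compartment)
  has <- substring(base, nchar(base) - nchar(suff) + 1) == suff
  base[has] <- substring(base[has], 1, nchar(base[has]) - nchar(suff)[has])
  paste0(base, "[", compartment, "]")
}

sbml_bounds <- function(rn, par_val, reversible) {
  lb_ref <- attr_any(rn, "lowerFluxBound", "fbc:lowerFluxBound")
  ub_ref <- attr_any(rn, "upperFluxBound", "fbc:upperFluxBound")
  if (!is.na(lb_ref) && lb_ref %in% names(par_val) &&
      !is.na(ub_ref) && ub_ref %in% names(par_val)) {
    return(c(par_val[[lb_ref]], par_val[[ub_ref]]))
  }
  # Level 2 COBRA style: kineticLaw parameters
  kl <- xml_first(rn, "kineticLaw")
  if (!is.null(kl)) {
    pars <- xml_all(kl, "parameter")
    ids <- vapply(pars, attr_any, "", "id")
    vals <- suppressWarnings(as.numeric(vapply(pars, attr_any, "", "value")))
    lb <- vals[match("LOWER_BOUND", ids)]
    ub <- vals[match("UPPER_BOUND", ids)]
    if (!is.na(lb) && !is.na(ub)) return(c(lb, ub))
  }
  if (reversible) c(-1000, 1000) else c(0, 1000)
}

sbml_gpr <- function(rn, gp_label) {
  gpa <- xml_first(rn, "geneProductAssociation")
  if (!is.null(gpa)) {
    kids <- xml2::xml_children(gpa)
    if (length(kids) == 0) return(NULL)
    return(fbc_to_gpr(kids[[1]], gp_label))
  }
  notes <- xml_first(rn, "notes")
  if (!is.null(notes)) {
    txt <- xml2::xml_text(notes)
    m <- regmatches(txt, regexpr("GENE_ASSOCIATION: *([^\n]*)", txt))
    if (length(m)) {
      rule <- trimws(sub("GENE_ASSOCIATION: *", "", m))
      if (nzchar(rule)) return(parse_gpr(rule))
    }
  }
  NULL
}

fbc_to_gpr <- function(node, gp_label) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    ref <- attr_any(node, "geneProduct", "fbc:geneProduct")
    gene <- if (ref %in% names(gp_label)) gp_label[[ref]] else sub("^G_", "", ref)
    return(gpr_leaf(gene))
  }
  if (nm %in% c("and", "or")) {
    args <- lapply(xml2::xml_children(node), fbc_to_gpr, gp_label = gp_label)
    return(gpr_node(nm, args))
  }
  stop("SBML parse error: unexpected element <", nm, "> in geneProductAssociation")
}

xml_all <- function(node, local) {
  xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", local))
}

xml_first <- function(node, local) {
  r <- xml2::xml_find_first(node, sprintf(".//*[local-name()='%s']", local))
  if (inherits(r, "xml_missing") || length(r) == 0) NULL else r
}

attr_any <- function(node, ...) {
  at <- xml2::xml_attrs(node)
  for (nm in c(...)) {
    hit <- at[names(at) == nm | sub("^[A-Za-z0-9]+:", "", names(at)) == nm]
    if (length(hit)) return(unname(hit[[1]]))
  }
  NA_character_
}
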