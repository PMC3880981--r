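#' Constraint-based metabolic model objects
#'
#' A `metabolic_model` holds compartments, metabolites, reactions with flux
#' bounds and GPR rules, and the biomass objective -- everything needed for
#' flux balance analysis on the stoichiometric matrix S (rows = metabolites,
#' columns = reactions).
#'
#' Compartments use the suffix convention `[c]` cytosol, `[p]` periplasm,
#' `[l]` thylakoid lumen, `[cx]` carboxysome, `[e]` extracellular; metabolite
#' identifiers carry the suffix (e.g. `glc[c]`). Exchange reactions are
#' recognised by a single-metabolite stoichiometry crossing the system
#' boundary.
#'
#' @name metabolic_model
NULL

COMPARTMENT_CODES <- c(c = "cytosol", p = "periplasm", l = "thylakoid lumen",
                       cx = "carboxysome", e = "extracellular")

#' Create a metabolite record
#'
#' @param id metabolite identifier including the compartment suffix,
#'   e.g. `"atp[c]"`.
#' @param name human-readable name.
#' @param formula elemental formula (e.g. `"C10H12N5O13P3"`) or `NA` when
#'   unknown.
#' @param charge integer charge or `NA`.
#' @param is_generic flag for non-specific acceptor / generic-lipid style
#'   metabolites; reactions touching these are filtered from drafts.
#' @return one-row data.frame.
#' @export
metabolite <- function(id, name = id, formula = NA_character_,
                       charge = NA_integer_, is_generic = FALSE) {
  data.frame(id = id, name = name, compartment = compartment_of(id),
             formula = as.character(formula), charge = as.integer(charge),
             is_generic = isTRUE(is_generic), stringsAsFactors = FALSE)
}

compartment_of <- function(id) {
  has <- grepl("\\[[A-Za-z]+\\]$", id)
  out <- rep(NA_character_, length(id))
  out[has] <- sub("^.*\\[([A-Za-z]+)\\]$", "\\1", id[has])
  out
}

#' Create a reaction
#'
#' Either `equation` or `stoich` must be given. Signed stoichiometric
#' coefficients follow the usual convention: negative = consumed,
#' positive = produced.
#'
#' @param id reaction identifier.
#' @param equation readable equation, e.g. `"2 A[c] + B[p] <=> C[c]"`;
#'   `"=>"` marks an irreversible reaction, an empty side a boundary drain
#'   (`"A[e] <=>"` is an exchange).
#' @param stoich named numeric vector of signed coefficients (names are
#'   metabolite ids); overrides `equation`.
#' @param lb,ub flux bounds; defaults are (-1000, 1000) for reversible and
#'   (0, 1000) for irreversible equations.
#' @param gpr GPR rule, as a string or a tree from [parse_gpr()].
#' @param ec character vector of EC numbers.
#' @param provenance one of `"reference"`, `"reference_transfer"`,
#'   `"seed_retrieval"`, `"essential_append"`, `"gapfill_addition"`.
#' @param sources annotation sources supporting the reaction.
#' @param dG,dG_err standard Gibbs free energy of reaction and its error
#'   (kcal/mol), `NA` when unknown.
#' @param subsystem subsystem/category tag (e.g. `"photosynthesis"`).
#' @param name display name.
#' @return a `model_reaction` object.
#' @export
reaction <- function(id, equation = NULL, stoich = NULL, lb = NULL, ub = NULL,
                     gpr = NULL, ec = character(0),
                     provenance = "reference", sources = character(0),
                     dG = NA_real_, dG_err = NA_real_,
                     subsystem = NA_character_, name = id) {
  if (is.null(stoich)) {
    if (is.null(equation)) stop("reaction '", id, "': need equation or stoich")
    eq <- parse_equation(equation)
    stoich <- eq$stoich
    if (is.null(lb)) lb <- if (eq$reversible) -1000 else 0
    if (is.null(ub)) ub <- 1000
  } else {
    stoich <- stoich[stoich != 0]
    if (is.null(lb)) lb <- -1000
    if (is.null(ub)) ub <- 1000
  }
  if (length(stoich) == 0) stop("reaction '", id, "': empty stoichiometry")
  if (lb > ub) stop("reaction '", id, "': lower bound exceeds upper bound")
  if (is.character(gpr)) gpr <- parse_gpr(gpr)
  structure(list(id = id, name = name, stoich = stoich,
                 lb = as.numeric(lb), ub = as.numeric(ub), gpr = gpr,
                 ec = unique(as.character(ec)), provenance = provenance,
                 sources = unique(as.character(sources)),
                 dG = as.numeric(dG), dG_err = as.numeric(dG_err),
                 subsystem = subsystem),
            class = "model_reaction")
}

#' Parse a readable reaction equation
#'
#' @param equation string such as `"2 A[c] + B[p] <=> C[c]"`.
#' @return list with `stoich` (named numeric) and `reversible` (logical).
#' @export
parse_equation <- function(equation) {
  arrow <- regmatches(equation, regexpr("<=>|=>|<=", equation))
  if (length(arrow) == 0) stop("equation has no arrow (<=>, => or <=): ", equation)
  sides <- strsplit(equation, "<=>|=>|<=")[[1]]
  lhs <- parse_eq_side(if (length(sides) >= 1) sides[1] else "")
  rhs <- parse_eq_side(if (length(sides) >= 2) sides[2] else "")
  if (arrow == "<=") { tmp <- lhs; lhs <- rhs; rhs <- tmp }
  stoich <- c(-lhs, rhs)
  stoich <- tapply(stoich, names(stoich), sum)
  stoich <- stats::setNames(as.numeric(stoich), names(stoich))
  stoich <- stoich[stoich != 0]
  if (length(stoich) == 0) stop("equation cancels to nothing: ", equation)
  list(stoich = stoich, reversible = arrow == "<=>")
}

parse_eq_side <- function(side) {
  side <- trimws(side)
  if (!nzchar(side)) return(stats::setNames(numeric(0), character(0)))
  terms <- trimws(strsplit(side, "[[:space:]]\\+[[:space:]]")[[1]])
  out <- numeric(0)
  for (tm in terms) {
    parts <- strsplit(tm, "[[:space:]]+")[[1]]
    if (length(parts) == 2 && grepl("^[0-9.]+$", parts[1])) {
      out[parts[2]] <- as.numeric(parts[1])
    } else if (length(parts) == 1) {
      out[parts[1]] <- 1
    } else {
      stop("cannot parse equation term: '", tm, "'")
    }
  }
  out
}

#' Render a reaction's stoichiometry as a readable equation
#' @param rxn a `model_reaction`.
#' @return equation string; the arrow reflects the bounds.
#' @export
format_equation <- function(rxn) {
  s <- rxn$stoich
  fmt <- function(v) {
    if (length(v) == 0) return("")
    paste(ifelse(abs(v) == 1, names(v),
                 paste(format(abs(v), trim = TRUE, digits = 10), names(v))),
          collapse = " + ")
  }
  arrow <- if (rxn$lb < 0 && rxn$ub > 0) "<=>" else if (rxn$ub <= 0) "<=" else "=>"
  if (arrow == "<=") arrow <- "<=>"  # written reversible; bounds columns carry direction
  trimws(paste(fmt(s[s < 0]), arrow, fmt(s[s > 0])))
}

#' Assemble a metabolic model
#'
#' @param id model identifier.
#' @param metabolites data.frame as built by [metabolite()] rows.
#' @param reactions list of [reaction()] objects.
#' @param biomass character vector of biomass reaction ids.
#' @param compartments compartment codes used; defaults to those appearing
#'   in the metabolite table.
#' @return a validated `metabolic_model`.
#' @export
metabolic_model <- function(id, metabolites, reactions, biomass = character(0),
                            compartments = NULL) {
  reactions <- stats::setNames(reactions, vapply(reactions, `[[`, "", "id"))
  if (is.null(compartments)) {
    compartments <- sort(unique(metabolites$compartment))
  }
  m <- structure(list(id = id, compartments = compartments,
                      metabolites = metabolites, reactions = reactions,
                      biomass = biomass),
                 class = "metabolic_model")
  validate_model(m)
  m
}

#' Validate model invariants
#'
#' Checks id uniqueness, that every reaction references declared metabolites,
#' that metabolite compartments are declared, and bound sanity.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly; errors describe the first violation.
#' @export
validate_model <- function(model) {
  mets <- model$metabolites
  if (anyDuplicated(mets$id)) {
    stop("duplicate metabolite ids: ",
         paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "))
  }
  rids <- vapply(model$reactions, `[[`, "", "id")
  if (anyDuplicated(rids)) {
    stop("duplicate reaction ids: ", paste(rids[duplicated(rids)], collapse = ", "))
  }
  bad_comp <- setdiff(mets$compartment, model$compartments)
  if (length(bad_comp)) {
    stop("metabolite compartment(s) not declared in model: ",
         paste(bad_comp, collapse = ", "))
  }
  for (r in model$reactions) {
    missing <- setdiff(names(r$stoich), mets$id)
    if (length(missing)) {
      stop("reaction '", r$id, "' references undeclared metabolite(s): ",
           paste(missing, collapse = ", "))
    }
    if (r$lb > r$ub) stop("reaction '", r$id, "': lb > ub")
    if (length(r$stoich) == 0) stop("reaction '", r$id, "': empty stoichiometry")
  }
  missing_bio <- setdiff(model$biomass, rids)
  if (length(missing_bio)) {
    stop("biomass reaction(s) not in model: ", paste(missing_bio, collapse = ", "))
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n",
      "  metabolites: ", nrow(x$metabolites),
      "  reactions: ", length(x$reactions),
      "  genes: ", length(model_genes(x)), "\n",
      "  compartments: ", paste(x$compartments, collapse = ", "), "\n",
      "  biomass: ", paste(x$biomass, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
print.model_reaction <- function(x, ...) {
  cat("<reaction> ", x$id, ": ", format_equation(x),
      "  [", x$lb, ", ", x$ub, "]\n", sep = "")
  if (!is.null(x$gpr)) cat("  gpr: ", deparse_gpr(x$gpr), "\n", sep = "")
  invisible(x)
}

#' Model accessors
#'
#' @param model a `metabolic_model`.
#' @return `reaction_ids()` / `metabolite_ids()`: character vectors;
#'   `model_genes()`: union of genes over all GPRs; `n_reactions()` /
#'   `n_metabolites()`: counts M and N; `is_exchange()`: named logical,
#'   `TRUE` for single-metabolite boundary reactions.
#' @export
reaction_ids <- function(model) names(model$reactions)

#' @rdname reaction_ids
#' @export
metabolite_ids <- function(model) model$metabolites$id

#' @rdname reaction_ids
#' @export
n_reactions <- function(model) length(model$reactions)

#' @rdname reaction_ids
#' @export
n_metabolites <- function(model) nrow(model$metabolites)

#' @rdname reaction_ids
#' @export
model_genes <- function(model) {
  sort(unique(unlist(lapply(model$reactions, function(r) gpr_genes(r$gpr)))))
}

#' @rdname reaction_ids
#' @export
is_exchange <- function(model) {
  vapply(model$reactions, function(r) length(r$stoich) == 1L, logical(1))
}

#' Stoichiometric matrix
#'
#' @param model a `metabolic_model`.
#' @return dense numeric matrix S (N metabolites x M reactions) with
#'   dimnames; fine at the model sizes this package targets.
#' @export
s_matrix <- function(model) {
  mids <- metabolite_ids(model)
  S <- matrix(0, nrow = length(mids), ncol = n_reactions(model),
              dimnames = list(mids, reaction_ids(model)))
  for (j in seq_along(model$reactions)) {
    r <- model$reactions[[j]]
    S[names(r$stoich), j] <- r$stoich
  }
  S
}

#' Add / remove reactions
#'
#' New metabolites appearing in added reactions are appended to the
#' metabolite table (with unknown formula/charge) unless already present.
#'
#' @param model a `metabolic_model`.
#' @param rxns list of [reaction()] objects.
#' @return the modified, revalidated model.
#' @export
add_reactions <- function(model, rxns) {
  if (inherits(rxns, "model_reaction")) rxns <- list(rxns)
  for (r in rxns) {
    new_mets <- setdiff(names(r$stoich), model$metabolites$id)
    for (mid in new_mets) {
      model$metabolites <- rbind(model$metabolites, metabolite(mid))
    }
    model$compartments <- sort(unique(c(model$compartments,
                                        model$metabolites$compartment)))
    model$reactions[[r$id]] <- r
  }
  validate_model(model)
}

#' @rdname add_reactions
#' @param ids reaction ids to drop.
#' @export
remove_reactions <- function(model, ids) {
  model$reactions <- model$reactions[setdiff(names(model$reactions), ids)]
  model$biomass <- setdiff(model$biomass, ids)
  model
}

# ---- duplicate detection -----------------------------------------------

#' Canonical key of a reaction's stoichiometry
#'
#' Direction-normalised: the key of a reaction equals the key of the same
#' reaction written reversed with negated coefficients, so duplicates are
#' found regardless of orientation.
#'
#' @param stoich named numeric vector of signed coefficients.
#' @return a string key.
#' @export
canonical_stoich_key <- function(stoich) {
  ser <- function(s) {
    s <- s[order(names(s))]
    paste(names(s), format(s, trim = TRUE, digits = 12), sep = ":", collapse = ";")
  }
  a <- ser(stoich); b <- ser(-stoich)
  if (a <= b) a else b
}

#' Find duplicate reactions
#'
#' Groups reactions identical under [canonical_stoich_key()] (same
#' metabolites and coefficients up to reversal). Singleton groups are
#' omitted.
#'
#' @param model a `metabolic_model`.
#' @return list of character vectors of reaction ids, one per duplicate
#'   group.
#' @export
find_duplicate_reactions <- function(model) {
  keys <- vapply(model$reactions, function(r) canonical_stoich_key(r$stoich), "")
  grp <- split(names(keys), keys)
  unname(grp[lengths(grp) > 1])
}

# ---- elemental balance -------------------------------------------------

#' Parse an elemental formula
#'
#' @param formula string like `"C6H12O6"`; element symbols are one capital
#'   letter optionally followed by a lowercase letter, counts default to 1.
#' @return named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) return(NULL)
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  toks <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  if (sum(nchar(toks)) != nchar(formula)) {
    stop("cannot parse formula: ", formula)
  }
  el <- gsub("[0-9]", "", toks)
  ct <- suppressWarnings(as.integer(gsub("[A-Za-z]", "", toks)))
  ct[is.na(ct)] <- 1L
  tapply(ct, el, sum)
}

#' Check charge and elemental balance of a reaction
#'
#' @param rxn a [reaction()].
#' @param metabolites metabolite table supplying `formula` and `charge`.
#' @return list with `status` (`"balanced"`, `"imbalanced"`, or `"unknown"`
#'   when any formula/charge is missing), `elements` (named net sums of the
#'   non-zero elements), and `charge` (net charge, `NA` if unknown).
#' @export
check_balance <- function(rxn, metabolites) {
  rows <- metabolites[match(names(rxn$stoich), metabolites$id), , drop = FALSE]
  if (anyNA(rows$id)) {
    stop("metabolite(s) missing from table: ",
         paste(setdiff(names(rxn$stoich), metabolites$id), collapse = ", "))
  }
  if (anyNA(rows$formula) || any(!nzchar(rows$formula))) {
    return(list(status = "unknown", elements = numeric(0), charge = NA_real_))
  }
  net <- numeric(0)
  for (k in seq_along(rxn$stoich)) {
    counts <- parse_formula(rows$formula[k])
    for (el in names(counts)) {
      net[el] <- (if (el %in% names(net)) net[el] else 0) +
        rxn$stoich[k] * counts[[el]]
    }
  }
  net <- net[abs(net) > 1e-9]
  chg <- if (anyNA(rows$charge)) NA_real_ else sum(rxn$stoich * rows$charge)
  balanced <- length(net) == 0 && !is.na(chg) && abs(chg) < 1e-9
  list(status = if (is.na(chg)) "unknown" else if (balanced) "balanced" else "imbalanced",
       elements = net, charge = chg)
}
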