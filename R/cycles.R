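#' Detect thermodynamically infeasible cycles
#'
#' With every exchange reaction closed, no internal reaction can carry
#' sustained flux unless it sits on a cycle that creates flux from
#' nothing -- a thermodynamically infeasible loop. Flux variability
#' analysis with unconstrained biomass is run and any internal reaction
#' whose minimum or maximum hits its own numeric bound (within `tol`) is
#' flagged, together with the unbounded direction(s).
#'
#' @param model a [metabolic_model()].
#' @param tol numeric slack on the bound test (default 1e-6).
#' @return data.frame with columns `id`, `min_hit`, `max_hit` -- one row
#'   per cycle member. Zero rows mean the model is loop-free.
#' @export
find_cycle_reactions <- function(model, tol = 1e-6) {
  ex <- names(which(is_exchange(model)))
  closed <- stats::setNames(rep(list(c(0, 0)), length(ex)), ex)
  internal <- setdiff(reaction_ids(model), ex)
  if (length(internal) == 0) {
    return(data.frame(id = character(0), min_hit = logical(0),
                      max_hit = logical(0), stringsAsFactors = FALSE))
  }
  ranges <- fva(model, reactions = internal, bounds = closed)
  lb <- vapply(model$reactions[internal], `[[`, 0, "lb")
  ub <- vapply(model$reactions[internal], `[[`, 0, "ub")
  min_hit <- !is.na(ranges$min) & ranges$min <= lb + tol & abs(lb) > tol
  max_hit <- !is.na(ranges$max) & ranges$max >= ub - tol & abs(ub) > tol
  keep <- min_hit | max_hit
  data.frame(id = ranges$id[keep], min_hit = min_hit[keep],
             max_hit = max_hit[keep], stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Repair thermodynamically infeasible cycles
#'
#' Iterates until [find_cycle_reactions()] is empty, applying three
#' ordered steps to cycle members of database provenance (the curated
#' reference reactions are never modified -- only retrieved reactions can
#' have created a loop):
#'
#' 1. *Gibbs free energy*: a member whose entire free-energy range is
#'    more than `dg_threshold` kcal/mol away from zero is restricted to
#'    the direction thermodynamics allows (ΔG − err > threshold ⇒
#'    reverse only; ΔG + err < −threshold ⇒ forward only).
#' 2. *Directionality*: remaining members are restricted opposite to
#'    their unbounded direction (the bound that FVA hit is clamped to
#'    zero, keeping the other direction).
#' 3. *Annotation support*: members still cycling that are supported
#'    solely by the lowest-confidence source (`"rast"`) are removed.
#'
#' @param model a [metabolic_model()]; reactions carry `dG`, `dG_err`,
#'   `provenance` and `sources`.
#' @param dg_threshold kcal/mol distance from zero required to trust a
#'   directionality call (default 4).
#' @param modifiable_provenance which provenance classes may be modified
#'   (default `"seed_retrieval"`).
#' @param max_iter safety cap on repair iterations.
#' @return list with the repaired `model`, a `log` data.frame (reaction,
#'   step, old/new bounds or removal) and `unrepairable` -- cycle members
#'   that persisted but were not eligible for modification (empty on
#'   success).
#' @export
repair_cycles <- function(model, dg_threshold = 4,
                          modifiable_provenance = "seed_retrieval",
                          max_iter = 50) {
  log <- list()
  note <- function(id, step, old_lb, old_ub, new_lb, new_ub, action) {
    log[[length(log) + 1L]] <<- data.frame(
      reaction = id, step = step, old_lb = old_lb, old_ub = old_ub,
      new_lb = new_lb, new_ub = new_ub, action = action,
      stringsAsFactors = FALSE)
  }
  dg_done <- character(0)
  clamped_once <- character(0)
  for (iter in seq_len(max_iter)) {
    cyc <- find_cycle_reactions(model)
    if (nrow(cyc) == 0) {
      return(list(model = model,
                  log = if (length(log)) do.call(rbind, log) else empty_repair_log(),
                  unrepairable = character(0)))
    }
    prov <- vapply(model$reactions[cyc$id], `[[`, "", "provenance")
    eligible <- cyc[prov %in% modifiable_provenance, , drop = FALSE]
    if (nrow(eligible) == 0) {
      return(list(model = model,
                  log = if (length(log)) do.call(rbind, log) else empty_repair_log(),
                  unrepairable = cyc$id))
    }
    changed <- FALSE
    # step 1: Gibbs free energy direction calls, once per reaction
    for (id in setdiff(eligible$id, dg_done)) {
      r <- model$reactions[[id]]
      if (is.na(r$dG) || is.na(r$dG_err)) next
      if (r$dG - r$dG_err > dg_threshold && r$ub > 0) {
        note(id, "gibbs_direction", r$lb, r$ub, r$lb, 0, "forward blocked")
        model$reactions[[id]]$ub <- 0
        changed <- TRUE
      } else if (r$dG + r$dG_err < -dg_threshold && r$lb < 0) {
        note(id, "gibbs_direction", r$lb, r$ub, 0, r$ub, "reverse blocked")
        model$reactions[[id]]$lb <- 0
        changed <- TRUE
      }
      dg_done <- c(dg_done, id)
    }
    if (changed) next
    # step 2: restrict each member opposite to its unbounded direction,
    # at most one direction call per reaction
    clamp <- function(k) {
      id <- eligible$id[k]
      r <- model$reactions[[id]]
      if (eligible$max_hit[k] && r$ub > 0) {
        note(id, "cycle_direction", r$lb, r$ub, r$lb, 0, "forward blocked")
        model$reactions[[id]]$ub <<- 0
        TRUE
      } else if (eligible$min_hit[k] && r$lb < 0) {
        note(id, "cycle_direction", r$lb, r$ub, 0, r$ub, "reverse blocked")
        model$reactions[[id]]$lb <<- 0
        TRUE
      } else FALSE
    }
    fresh <- which(!eligible$id %in% clamped_once)
    for (k in fresh) {
      if (clamp(k)) {
        clamped_once <- c(clamped_once, eligible$id[k])
        changed <- TRUE
      }
    }
    if (changed) next
    # step 3: a member whose first direction call did not break the loop and
    # that is supported only by the lowest-confidence source is removed
    rast_only <- eligible$id[vapply(model$reactions[eligible$id], function(r) {
      length(r$sources) > 0 && all(r$sources == "rast")
    }, logical(1))]
    if (length(rast_only)) {
      for (id in rast_only) {
        r <- model$reactions[[id]]
        note(id, "single_source_removal", r$lb, r$ub, NA_real_, NA_real_, "removed")
      }
      model <- remove_reactions(model, rast_only)
      next
    }
    # last resort: block the remaining direction of already-restricted members
    for (k in seq_len(nrow(eligible))) {
      if (clamp(k)) changed <- TRUE
    }
    if (changed) next
    return(list(model = model,
                log = if (length(log)) do.call(rbind, log) else empty_repair_log(),
                unrepairable = cyc$id))
  }
  stop("repair_cycles(): did not converge in ", max_iter, " iterations")
}

empty_repair_log <- function() {
  data.frame(reaction = character(0), step = character(0),
             old_lb = numeric(0), old_ub = numeric(0),
             new_lb = numeric(0), new_ub = numeric(0),
             action = character(0), stringsAsFactors = FALSE)
}
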