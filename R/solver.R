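#' Low-level LP/MILP interface
#'
#' Optimisation problems (FBA, FVA, gapfilling) are formulated in R and
#' solved by the HiGHS backend through a batched subprocess bridge, so a
#' whole flux-variability sweep or an alternative-optima enumeration costs
#' a single solver invocation. All problems share one convention:
#' minimise `c'x` subject to `row_lb <= A x <= row_ub`, `lb <= x <= ub`,
#' with optional integrality flags per variable.
#'
#' @param problems list of problem lists; each has `c`, `A` (list with
#'   0-based triplets `i`, `j`, `x` and dims `m`, `n`), `row_lb`,
#'   `row_ub`, `lb`, `ub`, optional `integrality` and `enumerate`.
#' @return list of solutions, each with `status` and (when optimal)
#'   `objective` and `x`, or `sets` for enumeration problems.
#' @keywords internal
solve_lp_batch <- function(problems) {
  if (length(problems) == 0) return(list())
  bridge <- system.file("python", "lp_bridge.py", package = "draftgsm")
  if (!nzchar(bridge)) stop("lp_bridge.py not found in installed package")
  python <- getOption("draftgsm.python", Sys.which("python"))
  if (!nzchar(python)) stop("no 'python' executable on PATH (needed for the HiGHS solver backend)")
  req <- tempfile(fileext = ".json")
  resp <- tempfile(fileext = ".json")
  on.exit(unlink(c(req, resp)), add = TRUE)
  jsonlite::write_json(list(problems = problems), req,
                       auto_unbox = TRUE, digits = NA, null = "null")
  status <- system2(python, c(bridge, req, resp), stdout = TRUE, stderr = TRUE)
  code <- attr(status, "status")
  if (!is.null(code) && code != 0) {
    stop("LP bridge failed (exit ", code, "):\n", paste(status, collapse = "\n"))
  }
  out <- jsonlite::fromJSON(resp, simplifyVector = FALSE)
  out$solutions
}

# Build the S v = 0 block for a model as 0-based triplets.
model_matrix_spec <- function(model) {
  mids <- metabolite_ids(model)
  met_index <- stats::setNames(seq_along(mids) - 1L, mids)
  i <- integer(0); j <- integer(0); x <- numeric(0)
  for (k in seq_along(model$reactions)) {
    s <- model$reactions[[k]]$stoich
    i <- c(i, unname(met_index[names(s)]))
    j <- c(j, rep(k - 1L, length(s)))
    x <- c(x, unname(s))
  }
  list(i = as.list(i), j = as.list(j), x = as.list(x),
       m = length(mids), n = length(model$reactions))
}

model_bounds <- function(model, bounds = NULL) {
  lb <- vapply(model$reactions, `[[`, 0, "lb")
  ub <- vapply(model$reactions, `[[`, 0, "ub")
  if (!is.null(bounds)) {
    for (id in names(bounds)) {
      if (!id %in% names(lb)) stop("bounds override for unknown reaction: ", id)
      lb[[id]] <- bounds[[id]][1]
      ub[[id]] <- bounds[[id]][2]
    }
  }
  list(lb = unname(lb), ub = unname(ub))
}

#' Flux balance analysis
#'
#' Maximises the objective flux subject to steady state (`S v = 0`) and
#' the flux bounds `v_min <= v <= v_max`.
#'
#' @param model a [metabolic_model()].
#' @param objective reaction id to maximise; defaults to the model's first
#'   biomass reaction.
#' @param bounds optional named list of `c(lb, ub)` overrides (growth
#'   condition / exchange bounds).
#' @param minimize maximise by default; set `TRUE` to minimise.
#' @return a `flux_solution`: list with `status` (`"optimal"`,
#'   `"infeasible"`, `"unbounded"`), `objective`, and named `fluxes`.
#' @export
fba <- function(model, objective = NULL, bounds = NULL, minimize = FALSE) {
  if (is.null(objective)) {
    if (length(model$biomass) == 0) stop("model has no biomass reaction; supply `objective`")
    objective <- model$biomass[1]
  }
  rids <- reaction_ids(model)
  if (!objective %in% rids) stop("objective reaction not in model: ", objective)
  A <- model_matrix_spec(model)
  bb <- model_bounds(model, bounds)
  cvec <- numeric(length(rids))
  cvec[match(objective, rids)] <- if (minimize) 1 else -1
  sol <- solve_lp_batch(list(list(
    c = cvec, A = A, row_lb = rep(0, A$m), row_ub = rep(0, A$m),
    lb = bb$lb, ub = bb$ub)))[[1]]
  if (sol$status != "optimal") {
    return(structure(list(status = sol$status, objective = NA_real_,
                          fluxes = NULL), class = "flux_solution"))
  }
  fl <- stats::setNames(as.numeric(unlist(sol$x)), rids)
  structure(list(status = "optimal",
                 objective = if (minimize) sol$objective else -sol$objective,
                 fluxes = fl),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> status: ", x$status, sep = "")
  if (x$status == "optimal") cat(", objective: ", format(x$objective))
  cat("\n")
  invisible(x)
}

#' Flux variability analysis
#'
#' For each reaction, minimises and maximises its flux under the FBA
#' constraints. With `fix_biomass = NULL` (the default) no constraint is
#' placed on growth, which is the mode used for cycle detection: any
#' internal reaction whose range hits its numeric bound can sustain flux
#' without nutrient input and sits on a thermodynamically infeasible
#' cycle.
#'
#' @param model a [metabolic_model()].
#' @param reactions reaction ids to scan (default all).
#' @param fix_biomass optional fraction in (0, 1]: biomass flux is first
#'   maximised and then constrained to at least that fraction of its
#'   optimum during the sweep.
#' @param bounds optional named list of `c(lb, ub)` overrides.
#' @return data.frame with columns `id`, `min`, `max`.
#' @export
fva <- function(model, reactions = NULL, fix_biomass = NULL, bounds = NULL) {
  rids <- reaction_ids(model)
  if (is.null(reactions)) reactions <- rids
  stopifnot(all(reactions %in% rids))
  A <- model_matrix_spec(model)
  bb <- model_bounds(model, bounds)
  if (!is.null(fix_biomass)) {
    opt <- fba(model, bounds = bounds)
    if (opt$status != "optimal") stop("cannot fix biomass: FBA status ", opt$status)
    bio_idx <- match(model$biomass[1], rids)
    bb$lb[bio_idx] <- max(bb$lb[bio_idx], fix_biomass * opt$objective)
  }
  probs <- list()
  for (id in reactions) {
    k <- match(id, rids)
    for (sense in c(1, -1)) {
      cvec <- numeric(length(rids)); cvec[k] <- sense
      probs[[length(probs) + 1L]] <- list(
        c = cvec, A = A, row_lb = rep(0, A$m), row_ub = rep(0, A$m),
        lb = bb$lb, ub = bb$ub)
    }
  }
  sols <- solve_lp_batch(probs)
  getobj <- function(s) if (s$status == "optimal") s$objective else NA_real_
  mins <- vapply(sols[seq(1, length(sols), by = 2)], getobj, 0)
  maxs <- -vapply(sols[seq(2, length(sols), by = 2)], getobj, 0)
  data.frame(id = reactions, min = mins, max = maxs,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Define a gapfilling problem
#'
#' Draft reactions are always active (their binary indicator is fixed at
#' one by omission); each candidate database reaction j gets a binary
#' y_j that, at zero, forces its flux to zero through
#' `v_min,j y_j <= v_j <= v_max,j y_j`. Biomass flux must reach a floor
#' set as a fraction of the maximum attainable when every candidate is
#' open.
#'
#' @param draft draft [metabolic_model()].
#' @param candidates list of candidate [reaction()]s (ids must be disjoint
#'   from the draft's).
#' @param biomass biomass reaction id; default the draft's first.
#' @param floor_frac biomass floor as a fraction of the all-candidates-open
#'   maximum (default 0.01, i.e. 1%).
#' @param bounds optional named list of `c(lb, ub)` growth-condition
#'   overrides.
#' @return a `gapfill_problem`: list with the union `model`, `draft_ids`,
#'   `candidate_ids`, `biomass`, `floor`, `vmax` (the all-open maximum),
#'   and `feasible` flag.
#' @export
gapfill_problem <- function(draft, candidates, biomass = NULL,
                            floor_frac = 0.01, bounds = NULL) {
  if (is.null(biomass)) {
    if (length(draft$biomass) == 0) stop("draft has no biomass reaction")
    biomass <- draft$biomass[1]
  }
  cand_ids <- vapply(candidates, `[[`, "", "id")
  overlap <- intersect(cand_ids, reaction_ids(draft))
  if (length(overlap)) {
    stop("candidate reactions already in draft: ", paste(overlap, collapse = ", "))
  }
  union_model <- add_reactions(draft, candidates)
  opt <- fba(union_model, biomass, bounds = bounds)
  vmax <- if (opt$status == "optimal") opt$objective else 0
  structure(list(model = union_model, draft_ids = reaction_ids(draft),
                 candidate_ids = cand_ids, biomass = biomass,
                 floor = floor_frac * vmax, vmax = vmax, bounds = bounds,
                 feasible = vmax > 1e-9),
            class = "gapfill_problem")
}

gapfill_milp_spec <- function(problem) {
  model <- problem$model
  rids <- reaction_ids(model)
  nr <- length(rids)
  cand_idx <- match(problem$candidate_ids, rids)  # 1-based flux columns
  ny <- length(cand_idx)
  A <- model_matrix_spec(model)
  bb <- model_bounds(model, problem$bounds)
  # floor on biomass
  bio <- match(problem$biomass, rids)
  bb$lb[bio] <- max(bb$lb[bio], problem$floor)
  i <- unlist(A$i); j <- unlist(A$j); x <- unlist(A$x)
  row_lb <- rep(0, A$m); row_ub <- rep(0, A$m)
  m <- A$m
  for (t in seq_len(ny)) {
    vj <- cand_idx[t]; yj <- nr + t
    # v_j - ub_j y_j <= 0
    i <- c(i, m, m); j <- c(j, vj - 1L, yj - 1L)
    x <- c(x, 1, -bb$ub[vj])
    row_lb <- c(row_lb, -1e30); row_ub <- c(row_ub, 0)
    m <- m + 1L
    # v_j - lb_j y_j >= 0
    i <- c(i, m, m); j <- c(j, vj - 1L, yj - 1L)
    x <- c(x, 1, -bb$lb[vj])
    row_lb <- c(row_lb, 0); row_ub <- c(row_ub, 1e30)
    m <- m + 1L
    # candidate flux freed; the coupling rows own the restriction
    bb$lb[vj] <- min(bb$lb[vj], 0)
    bb$ub[vj] <- max(bb$ub[vj], 0)
  }
  cvec <- c(numeric(nr), rep(1, ny))
  list(c = cvec,
       A = list(i = as.list(i), j = as.list(j), x = as.list(x),
                m = m, n = nr + ny),
       row_lb = row_lb, row_ub = row_ub,
       lb = c(bb$lb, numeric(ny)), ub = c(bb$ub, rep(1, ny)),
       integrality = c(numeric(nr), rep(1, ny)),
       y_index0 = nr + seq_len(ny) - 1L)
}

#' Minimal gapfilling additions
#'
#' Solves the mixed-integer program: minimise the number of candidate
#' reactions switched on, subject to steady state, bound coupling through
#' the binaries, and the biomass floor.
#'
#' @param problem a [gapfill_problem()].
#' @return list with `status`, `additions` (candidate ids in a global
#'   minimum set), `n_additions`, and `floor`; when even the full
#'   candidate pool cannot reach the floor, `status` is `"infeasible"`
#'   and `blocked_precursors` lists biomass substrates that cannot be
#'   produced.
#' @export
gapfill_min_additions <- function(problem) {
  stopifnot(inherits(problem, "gapfill_problem"))
  if (!problem$feasible) {
    return(list(status = "infeasible", additions = character(0),
                n_additions = NA_integer_, floor = problem$floor,
                blocked_precursors = diagnose_blocked_precursors(problem)))
  }
  spec <- gapfill_milp_spec(problem)
  y0 <- spec$y_index0; spec$y_index0 <- NULL
  sol <- solve_lp_batch(list(spec))[[1]]
  if (sol$status != "optimal") {
    return(list(status = sol$status, additions = character(0),
                n_additions = NA_integer_, floor = problem$floor))
  }
  x <- as.numeric(unlist(sol$x))
  picked <- problem$candidate_ids[x[y0 + 1L] > 0.5]
  list(status = "optimal", additions = sort(picked),
       n_additions = length(picked), floor = problem$floor)
}

#' Enumerate alternative gapfilling solutions
#'
#' Finds every minimal feasible addition set of size at most
#' `minimum + slack`, by repeatedly re-solving the MILP with integer cuts
#' `sum_{j in S} y_j <= |S| - 1` that exclude each found set together
#' with its supersets (a superset of a working set is not an informative
#' alternative).
#'
#' @param problem a [gapfill_problem()].
#' @param slack size allowance above the global minimum (the workflow
#'   default is 2: all alternatives within two reactions of the minimum).
#' @return list with `status`, `minimum`, and `sets` -- a list of sorted
#'   candidate-id vectors, the global minima first.
#' @export
enumerate_alternatives <- function(problem, slack = 2) {
  stopifnot(inherits(problem, "gapfill_problem"), slack >= 0)
  if (!problem$feasible) return(list(status = "infeasible", minimum = NA, sets = list()))
  spec <- gapfill_milp_spec(problem)
  y0 <- spec$y_index0; spec$y_index0 <- NULL
  spec$enumerate <- list(binary_idx = as.list(y0), slack = slack)
  sol <- solve_lp_batch(list(spec))[[1]]
  if (sol$status != "optimal") {
    return(list(status = sol$status, minimum = NA, sets = list()))
  }
  sets <- lapply(sol$sets, function(s) {
    sort(problem$candidate_ids[match(as.numeric(unlist(s)), y0)])
  })
  if (length(sol$sets) == 1 && length(sol$sets[[1]]) == 0) sets <- list(character(0))
  sizes <- lengths(sets)
  ord <- order(sizes, vapply(sets, paste, "", collapse = ","))
  list(status = "optimal", minimum = sol$minimum, sets = sets[ord])
}

diagnose_blocked_precursors <- function(problem) {
  model <- problem$model
  bio <- model$reactions[[problem$biomass]]
  precursors <- names(bio$stoich)[bio$stoich < 0]
  if (length(precursors) == 0) return(character(0))
  rids <- reaction_ids(model)
  A <- model_matrix_spec(model)
  bb <- model_bounds(model, problem$bounds)
  probs <- list()
  for (p in precursors) {
    # append a drain column for the precursor and maximise it
    k <- match(p, metabolite_ids(model)) - 1L
    Ai <- c(unlist(A$i), k); Aj <- c(unlist(A$j), A$n); Ax <- c(unlist(A$x), -1)
    probs[[p]] <- list(
      c = c(numeric(A$n), -1),
      A = list(i = as.list(Ai), j = as.list(Aj), x = as.list(Ax),
               m = A$m, n = A$n + 1L),
      row_lb = rep(0, A$m), row_ub = rep(0, A$m),
      lb = c(bb$lb, 0), ub = c(bb$ub, 1000))
  }
  sols <- solve_lp_batch(unname(probs))
  capacity <- vapply(sols, function(s) {
    if (s$status == "optimal") -s$objective else 0
  }, 0)
  precursors[capacity < 1e-9]
}

#' Apply a growth-condition bound set
#'
#' @param model a [metabolic_model()].
#' @param condition data.frame with columns `id`, `lb`, `ub`, or a named
#'   list of `c(lb, ub)`; typically exchange-reaction bounds describing an
#'   autotrophic or heterotrophic medium.
#' @return named list of bounds overrides suitable for the `bounds`
#'   argument of [fba()], [fva()] and [gapfill_problem()].
#' @export
condition_bounds <- function(model, condition) {
  if (is.data.frame(condition)) {
    out <- stats::setNames(
      lapply(seq_len(nrow(condition)),
             function(k) c(condition$lb[k], condition$ub[k])),
      condition$id)
  } else {
    out <- condition
  }
  unknown <- setdiff(names(out), reaction_ids(model))
  if (length(unknown)) {
    stop("growth condition references unknown reaction(s): ",
         paste(unknown, collapse = ", "))
  }
  out
}

#' Biomass yield per mole carbon fixed
#'
#' Maximises biomass under the given (typically photoautotrophic) bounds
#' and divides the optimum by the carbon uptake flux, giving mole biomass
#' per mole carbon fixed.
#'
#' @param model a [metabolic_model()].
#' @param bounds growth-condition bound overrides.
#' @param carbon_exchange id of the carbon-source exchange reaction
#'   (uptake is its negative flux).
#' @param objective biomass reaction id (default the model's first).
#' @return list with `yield`, `biomass_flux`, `carbon_uptake`, `status`.
#' @export
biomass_yield <- function(model, bounds = NULL, carbon_exchange = "EX_co2",
                          objective = NULL) {
  sol <- fba(model, objective = objective, bounds = bounds)
  if (sol$status != "optimal") {
    return(list(yield = NA_real_, biomass_flux = NA_real_,
                carbon_uptake = NA_real_, status = sol$status))
  }
  uptake <- -sol$fluxes[[carbon_exchange]]
  list(yield = if (uptake > 1e-9) sol$objective / uptake else NA_real_,
       biomass_flux = sol$objective, carbon_uptake = uptake,
       status = "optimal")
}
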