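---
title: "Reconstructing draft metabolic models by homology transfer and multi-source annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing draft metabolic models by homology transfer and multi-source annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A genome-scale metabolic model (GSM) couples three layers: a
stoichiometric matrix S (metabolites × reactions), flux bounds encoding
reversibility and medium composition, and gene-protein-reaction (GPR)
Boolean rules stating which gene combinations enable each reaction. Flux
balance analysis (FBA) then predicts phenotype by maximising biomass flux
subject to steady state, `S v = 0`, and `v_min ≤ v ≤ v_max`.

Curating a GSM by hand takes months to years, while for most microbes only
a few hundred reviewed gene annotations exist. When a well-curated model of
a *close relative* is available, most of the work can be inherited: the
curated reactions, their GPR logic, their compartment assignments and the
biomass composition. `draftgsm` implements that inheritance plus the
machinery needed to make the result a usable model: annotation-driven
extension beyond the reference chemistry, mixed-integer gapfilling to
biomass, and removal of thermodynamically infeasible cycles.

## Homology transfer

Orthology is approximated by bidirectional best hits (BBH): a reference
gene r and target gene t pair up when each is the other's best BLAST hit
and both directions pass the e-value cutoff. Within one query, ties are
broken by e-value, then bit score, then subject identifier, so the map is
deterministic. We require *both* directions to pass the cutoff — the
stricter of the two possible readings — because a weak reverse hit is
exactly the false-positive signature BBH is meant to guard against.

Two cutoffs matter. Transfer uses a conservative `1e-30`; a relaxed pass at
`1e-10` is used only late, to complete GPRs of reactions that are already
in the model on other evidence (photosynthesis, biomass necessity) and are
missing one or two subunit orthologs. Both are configuration values.

A reference reaction transfers when its GPR evaluates true with the mapped
genes treated as present: one isozyme in an OR suffices; an AND complex
needs every subunit. The transferred GPR is rewritten in target gene ids,
pruning branches containing unmapped genes. We do not invent placeholder
genes for half-mapped complexes: a pruned OR branch merely narrows the
rule, while a fabricated subunit id would poison downstream gene-deletion
analyses. Reactions with *no* GPR (exchanges, diffusion, the biomass
pseudo-reaction, spontaneous chemistry) never transfer on homology — there
is no evidence to evaluate — and instead enter through the essential-append
and gapfilling stages, which carry their own justification.

## Annotation reconciliation

Gene→EC claims come from the reference model itself (through the ortholog
map) and any number of external tables. Only fully specified EC numbers
(four numeric fields) are accepted; wildcard ECs would drag in whole enzyme
classes. Disagreements are resolved in a fixed order:

1. **EC transfer history.** Enzyme Commission numbers get reassigned over
   time; claims are normalised through a transitively closed old→new table
   before being compared, which dissolves purely nomenclatural conflicts.
2. **Subset rule.** If every EC proposed by non-reference sources is
   contained in the reference model's set for that gene, the gene is not
   considered conflicting and the reference set is used. This runs before
   the filters so that curated reference annotations are never eroded by
   an absence in weaker sources.
3. **Evidence exclusions.** A user-supplied table of (EC, reason) — the
   stand-in for a literature/protein-family lookup, which is inherently a
   manual step — removes claims incompatible with the organism.
4. **Generic/absent metabolites.** ECs acting on generic acceptors or on
   compounds known to be absent from the organism are removed.
5. **Confidence order.** Whatever still disagrees is settled by source
   rank (default: reference model, then Uniprot-style, NCBI-style,
   RAST-style — ordered by how individually each source's annotations are
   reviewed).

Resolved sets never contain excluded or generic-flagged ECs regardless of
the route taken, and the full trace (steps applied, basis, conflict flag)
is kept per gene.

## Retrieval, essential reactions, deduplication

Resolved ECs are matched against the reference model first — its copies
carry curated GPRs and compartments — and only the leftovers query the
universal database, restricted to entries flagged charge- and
elementally-balanced. GPRs for database reactions are built Autograph
style from annotation designation strings: genes sharing a designation are
isozymes (OR), distinct designations are complex subunits (AND across
groups). Designations are compared after case/whitespace normalisation
only; no fuzzy matching, because a partial string overlap is weak evidence
of shared function. A gene listed under two designations joins both
groups.

Photosynthesis, oxidative phosphorylation and diffusion-transport
reactions are appended from the reference when absent: an organism that
grows autotrophically must have them whether or not orthologs were found.
Duplicates are detected by a canonical stoichiometric key — sorted
metabolite:coefficient pairs, orientation-normalised so a reaction and its
reverse hash identically — and collapse onto the reference-derived copy,
which carries the richer annotation.

## Gapfilling

Draft models usually cannot produce biomass: exchanges and
no-GPR reactions do not transfer. With binaries y_j on candidate reactions
(draft reactions have y fixed at 1 by omission), the MILP minimises the
number of additions subject to steady state, bound coupling
`v_min,j y_j ≤ v_j ≤ v_max,j y_j`, and a biomass floor. The floor defaults
to 1 % of the maximum achievable with every candidate open; it is a
configuration value. Candidates in the pipeline are the reference
reactions not already in the draft, and the run is repeated per growth
condition (autotrophic, then heterotrophic bound sets), accumulating
additions.

Alternative optima matter because the choice among them is an evidence
question, not a numerical one. We enumerate with integer cuts
`Σ_{j∈S} y_j ≤ |S| − 1` for each found set S, under a size budget of
minimum + slack (slack defaults to 2). This cut excludes S *and its
supersets*, so the enumeration returns exactly the minimal feasible sets
within the budget: since opening extra reactions can only relax the
problem, every feasible support contains a minimal one, and supersets of a
working set are not informative alternatives. The chosen set is the one
with the most members supported by evidence (a reference GPR or a resolved
EC), ties going to the smaller set.

Solver note: FBA, FVA and the MILP are formulated in R and solved by
HiGHS through a batched subprocess bridge (scipy's `milp`), one solver
invocation per FVA sweep or enumeration run. Tolerances follow the
backend's defaults (primal feasibility ~1e-9, integrality 1e-6); steady
state is verified at 1e-6 in tests. Results are deterministic for a given
problem.

## Cycle repair

A thermodynamically infeasible cycle is a set of internal reactions that
can carry flux with every exchange closed — creating flux from nothing.
Detection runs FVA with exchanges closed and biomass unconstrained
(growth constraints would only mask loops) and flags any internal reaction
whose minimum or maximum reaches its own numeric bound within 1e-6.
Exchanges are closed during detection because open uptakes legitimately
support large fluxes; only the closed-system signature is diagnostic.

Repair only ever touches database-derived reactions — the curated
reference is trusted — and applies three ordered steps, re-running
detection after each round of modifications:

1. A member whose ΔG range lies entirely more than 4 kcal/mol from zero
   (|ΔG| − error > 4) is restricted to the thermodynamically allowed
   direction. The 4 kcal/mol margin is configurable.
2. Remaining members are restricted opposite to their unbounded direction
   — the bound FVA hit is clamped to zero, keeping the other direction.
   Each reaction receives at most one such call, the minimal restriction
   that removes the observed circulation.
3. Members still cycling after their direction call and supported solely
   by the lowest-confidence source are deleted. As a last resort the
   remaining direction of already-restricted members is closed; a cycle
   composed of reference reactions is reported unrepairable instead.

Repair is idempotent, logs every modification (old and new bounds, or
removal), and the biomass optimum after repair is reported by the
pipeline.

## Model comparison

Reaction sets are compared with Similarity = A² / ((A+B)(A+C)), A shared
and B, C unique counts — the squared Ochiai coefficient. It is bounded in
[0, 1], symmetric, 1 exactly for identical sets and 0 for disjoint ones,
which is what a between-model heatmap needs. Reactions are matched by
identifier (the workflow keeps one namespace), with a canonical-stoichiometry
fallback for renamed copies; exchange reactions count unless
`internal_only` is set.

## The synthetic fixture world

The generator builds everything the pipeline consumes, with ground truth
recorded: a ~30-reaction photoautotroph-style reference (photon/CO₂/O₂/
ammonium/glucose/water exchanges, diffusion and carrier transports, a
photosystem, respiration, carbon fixation, five biomass precursors, random
side reactions; mixed AND/OR GPRs over 24 genes), BLAST tables with
planted mutual best hits below 1e-30, relaxed-only pairs between 1e-30 and
1e-10, worse-ranked secondary hits and decoys above both cutoffs;
annotation tables with per-source coverage dropout (85 % / 60 % / 85 %) and
the five conflict archetypes planted on dedicated genes; and a universal
database with novel-EC entries, one unbalanced decoy, a planted
three-reaction loop (one member at ΔG = +8 ± 2 kcal/mol) reachable only
through single-source annotations, and a gapfill rescue reaction. Default
fractions (70 % strict orthologs, 15 % relaxed) sit in the range where a
draft transfers most but not all of the reference — the regime the
workflow exists for. Loop and novel ECs are attached to genes without
reference orthologs, since that is how single-source chemistry enters real
drafts.

What the fixtures do *not* emulate: sequence-level realism (e-values are
drawn, not computed from alignments), genome-scale size (tens, not
thousands, of reactions — chosen so the full suite, including brute-force
MILP verification, runs in minutes), mass-balanced stoichiometry in the
random side reactions, and the multi-equation biomass descriptions of real
cyanobacterial models (the fixture biomass is a five-precursor drain).
Passing tests therefore demonstrate the correctness of the algorithms and
bookkeeping, not the biological fidelity of any particular reconstruction.

## Numerical and design choices

* Default flux bounds are ±1000 (0..1000 irreversible), the community
  convention; equations carry direction, bounds columns override.
* The GPR grammar is COBRA's: case-insensitive `and`/`or`, parentheses,
  `and` binding tighter than `or`.
* Bound-hit detection and steady-state residuals use 1e-6; LP bound
  clamping treats |b| ≥ 1e30 as infinite.
* The gapfill enumeration returns minimal sets (superset-excluding cuts);
  see above for why supersets are uninformative.
* Duplicate preference order: reference transfer, essential append,
  database retrieval, gapfill addition.
* Empty-GPR reference reactions are excluded from homology transfer by
  design and re-enter via essential append or gapfilling.
* SBML identifiers are mangled COBRA-style (`M_x_c`, `R_id`, `G_gene`
  with the verbatim gene id in `fbc:label`); ids made of word characters
  plus a compartment suffix round-trip exactly.

## Limitations

* The universal database is consumed as a flat file; there is no live
  database client, and metabolite cross-database reconciliation is out of
  scope (the workflow assumes the reference and database share notation).
* Literature/protein-family screening is represented by the exclusions
  table; the package does not query external services.
* Cycle repair implements the ordered bound-restriction procedure, not a
  global loopless-FBA formulation.
* Published reconstructions distributed as journal supplements are not
  bundled; the validation test recognises them if placed under
  `inst/extdata/published/` and otherwise exercises the same statistics
  and yield machinery on a synthetic model.
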