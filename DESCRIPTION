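Package: draftgsm
Title: Draft Genome-Scale Metabolic Model Reconstruction from a Curated Reference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automated reconstruction of genome-scale metabolic models for
    organisms closely related to a species with a curated model. Reactions are
    transferred from the reference by evaluating gene-protein-reaction (GPR)
    Boolean rules under bidirectional-best-hit ortholog maps, gene-to-EC
    annotations from multiple sources are reconciled by an ordered conflict
    resolution procedure, additional balanced reactions are retrieved from a
    universal (SEED-like) reaction database, biomass production is restored by
    mixed-integer gapfilling, thermodynamically infeasible cycles are removed
    by an iterative flux-variability repair, and finished models are compared
    by reaction-content similarity. Includes flux balance analysis and flux
    variability analysis, SBML and tabular model input/output, and a synthetic
    fixture generator producing complete input bundles with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
SystemRequirements: python (>= 3.8) with numpy and scipy (HiGHS backend) on PATH
Config/testthat/edition: 3
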