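Package: protonMCO
Title: Automated Robust Proton Therapy Planning with Transmission Beams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale pipeline for fully automated robust intensity-modulated
    proton therapy (IMPT) planning with optional high-energy transmission beams,
    for nasopharynx-like geometries. Generates seeded synthetic voxel phantoms,
    computes analytic pencil-beam dose-influence matrices for setup/range error
    scenarios, optimizes spot weights by lexicographic (wish-list) multi-criteria
    linear programming with minimax robustness and sparsity-induced spot
    selection, and evaluates plans with DVH statistics, voxel-wise min/max
    robustness metrics, Paddick conformity indices, logistic NTCP models and
    paired Wilcoxon signed-rank comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    yaml,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    pracma
SystemRequirements: python (>= 3.8) with numpy and scipy on PATH (LP backend)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
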