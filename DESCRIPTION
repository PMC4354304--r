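Package: pathflux
Title: Pathway Gapfilling, Transcriptome-Based Reduction and Flux Fitting
    for Constraint-Based Metabolic Models
Version: 0.1.0
Authors@R:
    person("pathflux", "developers", email = "pathflux@example.org",
           role = c("aut", "cre"))
Description: A constraint-based modeling toolkit for genome-scale metabolic
    models.  Implements slack-flux pathway gapfilling (a mixed-integer
    program that activates as many gene-associated reactions as possible
    while adding a minimum-cost set of database reactions), transcriptome-
    driven model reduction (gene-protein-reaction aware expression scoring
    with a high/low threshold and an optimization that prunes low-expression
    reactions while preserving growth), and quadratic-programming fitting of
    model fluxes to measured fluxomics with Spearman evaluation and
    blocked-reaction statistics.  Reads and writes SBML Level 3 (FBC) and a
    simple TSV dialect, and ships deterministic synthetic-fixture generators
    so the whole pipeline is testable without external data.  Linear,
    mixed-integer and quadratic programs are solved through a bundled
    SciPy/HiGHS backend.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: Python (>= 3.8) with numpy and scipy (>= 1.9) on PATH
Config/testthat/edition: 3
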