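Package: diazogem
Title: Constraint-Based Metabolic Modelling of Aerobic Diazotrophs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Genome-scale metabolic model (M-model) tooling for
    nitrogen-fixing bacteria: SBML-FBC and cobra-JSON model input/output,
    flux balance analysis and parsimonious FBA on a built-in
    bounded-variable simplex solver, reconstruction quality control
    (element and charge balance, closed-exchange energy-cycle detection,
    gene-protein-reaction deletion screens), homology-driven curation and
    parsimony gap-filling, biomass-objective construction from proteome
    amino-acid composition, phenotype-microarray growth screens with
    confusion statistics, elemental carbon/nitrogen flux partitioning per
    subsystem, and alginate/polyhydroxybutyrate production analysis. A
    deterministic synthetic toy diazotroph network with ground-truth
    manifests exercises the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    Matrix,
    Biostrings,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
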