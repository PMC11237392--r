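Package: hybridgem
Title: Hybrid-Aware Genome-Scale Metabolic Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Constraint-based metabolic modeling for interspecies hybrid
    organisms. Builds a hybrid genome-scale model from a template model plus
    parental ortholog tables, rewriting gene-protein-reaction (GPR) rules with
    allele redundancy; runs flux balance analysis (FBA), flux variability
    analysis (FVA) and gene/reaction knockout essentiality scans on a
    bounded-variable simplex core; constrains reaction bounds from RNA-seq
    data via TPM normalization and recursive Boolean GPR aggregation
    (OR = sum, AND = min); and attributes each reaction's expression support
    to parental sub-genomes. Reads and writes SBML Level 3 with the fbc
    extension and a simple tabular model dialect, and ships deterministic
    generators for toy models, ortholog tables and expression profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xml2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
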