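Package: gemflux
Title: Integrated Metabolic Profiling with Genome-Scale Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based metabolic profiling that integrates transcriptomic
    and nutrient-availability data into a genome-scale metabolic model (GEM).
    Gene expression tables are converted into per-reaction Reaction Activity
    Scores (RAS) through gene-protein-reaction (GPR) rules (AND = min,
    OR = sum); medium composition and spent-medium measurements are converted
    into Maximal Uptake Rates (MUR) for exchange reactions. Both are mapped
    onto flux bounds through a single scale factor alpha, which is calibrated
    against observed growth rates. Condition-specific models are then analysed
    with flux balance analysis (FBA) and flux variability analysis (FVA) to
    predict biomass synthesis flux and nutrient uptake/secretion ranges.
    Includes SBML (Level 3 + FBC) and COBRA-JSON model input/output, a seeded
    synthetic-fixture generator for end-to-end testing, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Matrix,
    methods,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
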