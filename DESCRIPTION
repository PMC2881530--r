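Package: haloflux
Title: Constraints-Based Analysis of Haloarchaeal Growth on a Single Carbon Source
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constraints-based (flux balance) analysis of microbial
    growth on a single carbon source, modelled on aerobic acetate growth of the
    haloalkaliphilic archaeon Natronomonas pharaonis. Provides a metabolic
    network data model with elemental/charge balance auditing, gene-logic
    evaluation and evidence reporting; SBML and tabular network readers and
    writers; construction of a biomass (growth) pseudo-reaction from
    composition measurements (total organic carbon and per-amino-acid slopes,
    combined-pool splitting, GC-proportional nucleotide allocation,
    reference-scaled minor components, maintenance ATP); a linear-programming
    flux balance core with reaction-class constraints; phenotype sweeps over
    the substrate:oxygen uptake ratio and maintenance energy with feasibility
    bounds, optimality curves and near-optimality scores; carbon-fate
    accounting of growth experiments; and synthetic-data generators (balanced
    toy networks with closed-form optima, simulated growth series, a
    vertex-enumeration LP oracle) that make every stage testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
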