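Package: phenolprofiler
Title: Cross-Database Characterization of Flavonoids and Phenolic Acids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An integrative characterization pipeline for dietary polyphenols
    (flavonoids and phenolic acids). Reconciles compound records across
    database extracts by InChIKey, computes the classical oral drug-likeness
    descriptor panel (molecular weight, Crippen logP, hydrogen-bond donors
    and acceptors, rotatable bonds, Ertl topological polar surface area,
    aromatic rings, stereocentres) from SMILES with a native molecular-graph
    engine, scores compounds with a from-first-principles implementation of
    the Quantitative Estimate of Drug-likeness (QED) and a fragment-sum
    drug-likeness aggregator, standardizes ChEMBL-style bioactivity records
    to pChEMBL values with class-level comparisons, maps food-source
    concentrations into standardized per-food and per-group profiles with
    concentration tiers, and generates fully synthetic compound, activity,
    and food tables with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
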