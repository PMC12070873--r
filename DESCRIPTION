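Package: sgeRFI
Title: Social Genetic Effects on Residual Feed Intake in Group-Housed Pigs
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for estimating direct and social (indirect) genetic
    effects on residual feed intake from electronic feeder data in
    group-housed pigs. Includes processing of per-visit feeder logs with
    day-level quality control, derivation of feeding-behaviour and growth
    traits, displacement-success dominance scoring, residual feed intake
    with fixed literature coefficients, pedigree validation and the
    additive relationship matrix, an animal model with correlated direct
    and social genetic effects fitted by average-information REML with
    BLUP breeding values, HPD-based selection of extreme animals with
    group comparison, nine-quadrant transcript-protein concordance
    classification, and a synthetic-data generator emulating the study
    design so the whole pipeline is testable without raw records.
License: MIT
Encoding: UTF-8
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
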