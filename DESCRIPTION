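Package: pollenniche
Title: Dual-Locus Pollen Metabarcoding Profiles and Nutritional Niche
    Summaries for Solitary Bees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genus-level pollen diet profiling from dual-locus
    (ITS1/ITS2) amplicon metabarcoding and for protein-to-lipid nutritional
    niche analysis of bee pollen provisions. Includes a reference-barcode
    decontamination cascade that flags mislabeled sequences against plant
    and non-plant contrast databases, a semi-global (free end gap) aligner
    with top-hit lowest-common-ancestor read assignment, dual-locus
    maximum-count genus profiling with sample quality control and
    proportion thresholds, protein:lipid ratio and diet-formulation
    arithmetic, rearing-outcome survival summaries, and a synthetic-data
    module that simulates reference databases with planted mislabels,
    amplicon read sets from known genus mixtures, provision nutrition
    tables, and rearing outcomes for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
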