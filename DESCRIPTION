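Package: shapefold
Title: SHAPE-Directed RNA Secondary Structure Inference with Fragment,
    Resampling and Covariation Support
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers long noncoding RNA secondary structure from chemical
    probing data. Implements SHAPE-reactivity-directed thermodynamic folding
    (minimum free energy, bounded suboptimal ensembles and McCaskill
    partition function under a nearest-neighbor energy model with
    Deigan-style pseudo-energies), shotgun secondary structure (3S)
    fragment-correlation analysis for model selection, jackknife resampling
    confidence, per-nucleotide Shannon entropy and well-defined-domain
    detection, DMS reactivity validation, and a mutual-information
    covariation screen with a permutation null over structure-annotated
    alignments. Ships a reagent-faithful synthetic probing-data generator so
    the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    tools,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
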