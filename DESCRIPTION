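Package: mecap
Title: Multi-Epitope AP-MS Interactor Calling and BN-PAGE Complexome Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A label-free quantitative proteomics pipeline for identifying
    native membrane-protein complexes. Implements MS1-level m/z recalibration,
    retention-time alignment by robust local regression against dynamically
    computed reference times, tolerance-based peak-volume assignment, protein
    abundance estimation (abundance-norm values from in-silico tryptic
    digests), specificity/consistency interactor calling against stringent
    negative controls (target-unrelated antibody and knockout purifications),
    and blue-native gel complexome profiling with marker-calibrated sigmoidal
    slice-to-mass conversion. Ships seeded synthetic-data generators that
    plant known ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml,
    zoo
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
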