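Package: jaenet
Title: Peri-Ictal EEG Phase-Locking Networks and Weighted Graph Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds phase-locking-value (PLV) functional connectivity
    networks from multichannel scalp EEG across peri-ictal seizure states
    (inter-ictal, pre-ictal, ictal, post-ictal) and healthy-control rest,
    computes weighted graph-theory metrics (clustering coefficient,
    characteristic path length, global and local efficiency, small-world
    index against a weight-permutation null ensemble), and runs the full
    state and group statistical comparison (edgewise tests with FDR,
    covariate-adjusted group models, repeated-measures ANOVA with
    Tukey-Kramer post hoc). Includes EDF/EDF+ input and output, Hamming
    windowed zero-phase FIR preprocessing, and a synthetic 19-channel EEG
    cohort generator with ground-truth state-dependent phase coupling and
    spike-wave ictal morphology, so the whole pipeline is testable without
    clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
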