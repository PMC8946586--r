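Package: mplexfc
Title: Multilayer Frequency-Band Brain Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Builds multiplex (multilayer) functional brain networks from
    parcellated BOLD time series, one layer per slow frequency band
    (slow5-slow2), and quantifies cross-frequency segregation and
    integration with a multilayer clustering coefficient (MCC) and the
    entropy of the multiplex degree (EMD). Provides zero-phase band-pass
    decomposition, Pearson connectivity, proportional-sparsity
    binarization, supra-adjacency assembly, single-layer clustering and
    local efficiency, AUC aggregation over a sparsity grid,
    resting-state-network summaries, group comparisons with
    Benjamini-Hochberg FDR correction, symptom-score correlations, and a
    synthetic two-group cohort generator for validation and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    pracma,
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
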