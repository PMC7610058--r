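Package: erpconsensus
Title: Multi-Subject Consensus Clustering and Time-Window Detection for ERP Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Stabilized multi-subject (multiset) consensus clustering of
    spatiotemporal event-related potential (ERP) data and detection of
    measurement time windows from the resulting cluster maps. Provides a
    registry of base clusterers used in EEG microstate analysis (modified
    k-means, AAHC, correlation hierarchical clustering, k-means, fuzzy
    c-means, 1-D self-organizing maps, diffusion-map spectral clustering),
    co-association/CSPA consensus with a repetition-count stabilization rule,
    benchmark-based method selection, inner-similarity time-window detection,
    a calibrated multi-subject ERP simulator with signed-area ground-truth
    windows, and an evaluation layer (TOST equivalence tests, balanced 2x2
    repeated-measures/mixed ANOVA, multi-run robustness summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
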