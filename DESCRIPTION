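Package: promstate
Title: Promoter Chromatin State Classification from ChIP-Seq Windows
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Window-based analysis of promoter chromatin state from aligned
    ChIP-seq reads. Calibrates per-library Poisson significance thresholds for
    fixed-width promoter windows, classifies genes by H3K4me3/H3K27me3 valency
    (monovalent, bivalent, unmarked), computes RNA polymerase II stalling
    indices and active/stalled classes, derives expression categories from
    RPKM tables and compares them with microarray present/absent calls, calls
    read-count islands against a Poisson background with a Monte-Carlo score
    null, and performs sequencing-depth saturation analysis by read
    subsampling. A synthetic-data generator plants ground-truth chromatin
    states so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    jsonlite,
    optparse
Config/testthat/edition: 3
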