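Package: promoccupy
Title: Promoter Occupancy of Broad Histone-Mark ChIP-Seq Peaks and
    Companion Myogenesis Assay Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies occupancy of broad ChIP-seq peaks (for example
    H3K27me2/3) over strand-aware promoter windows: treatment-specific
    peak sets, percent overlap of peaks with windows spanning 3000 bp
    upstream to 300 bp downstream of each transcription start site,
    peak-centered read-density matrices from bedGraph coverage, and
    hypergeometric / EASE over-representation of occupied-promoter gene
    lists against GMT gene-set collections. Also provides the companion
    bench statistics of a myogenesis study design: geometric-mean
    reference-gene qPCR normalization with max-to-1 scaling, muscle-fiber
    cross-sectional-area morphometry with 3-SD size classes, labeled-cell
    count ratios, and group comparisons. A seeded synthetic-data
    generator emulates every input so the full pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    multcomp,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
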