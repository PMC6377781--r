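Package: funheatmap
Title: Symbolic Pattern Recognition for Time-Series Differential Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Clusters time-series differential-expression profiles by a
    symbolic representation: per-time-point fold changes (optionally gated
    by p-values) are discretized into '+', '-' and '0' symbols and
    concatenated into pattern keys, which partition genes into pattern
    groups; each group is further decomposed into trend sub-groups by the
    direction of change between time points. Supports multi-cohort
    combination with synchronized-gene queries and Venn-style region
    stratification, time-point consolidation by means, pathway-database
    deduplication via an overlap-rate distance with average-linkage
    clustering, and one-sided hypergeometric pathway enrichment. Includes
    seeded synthetic-data generators, delimited-text exporters and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
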