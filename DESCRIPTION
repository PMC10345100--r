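Package: fairphen
Title: FAIRification and Integration of Multi-Environment Plant Phenotyping Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models plant phenotyping experiments following the MIAPPE 1.1
    metadata checklist together with sparse tab-delimited observation tables
    and daily weather series, validates them against the checklist's
    structural rules, and serializes both metadata and data losslessly to
    RDF (Turtle) using a PPEO-style vocabulary for phenotyping and an
    AEMET-style vocabulary for weather. Builds and crawls a four-level FAIR
    Data Point hierarchy (root, catalog, dataset, distribution) with MIAPPE
    investigation summaries embedded at the dataset level so datasets are
    assessable without opening their distributions. Implements the
    integration milestones of a multi-environment potato trial reuse
    scenario: study summaries, genotype overlap, nearest-weather-station
    matching, per-genotype trait aggregation, cumulative photo-beta thermal
    time, and genotype stability lines, each computable from in-memory
    objects, serialized graphs, or a SPARQL engine. A seeded generator
    produces deposit-shaped synthetic fixtures with a ground-truth ledger.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rlang,
    jsonlite,
    ggplot2,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
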