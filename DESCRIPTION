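Package: nragewpn
Title: Protein Complex Detection in Confidence-Weighted PPI Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects protein complexes from protein-protein interaction
    (PPI) networks. Interaction confidence is scored by blending a
    resource-allocation topological index with the Pearson correlation of
    gene-expression profiles; complex cores are mined under weighted-density
    and hop-diameter constraints and expanded with second-order neighbor
    attachments. Includes a full complex-prediction evaluation battery
    (sensitivity/PPV/accuracy, Jaccard and neighborhood-affinity
    precision/recall, maximum matching ratio, fraction match, separation and
    composite scores) and a seeded synthetic-data generator with planted
    complexes and co-expressed member profiles.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
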