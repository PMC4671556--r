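Package: bicnet
Title: Protein Complex Detection in Dynamic Protein Interaction Networks via
    Expression Biclustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects protein complexes in protein-protein interaction (PPI)
    networks whose dynamics are modelled by biclustering a companion gene
    expression matrix. Implements mean-squared-residue (Cheng-Church style)
    biclustering and a Pearson-distance k-means baseline, per-bicluster PPI
    subnetwork extraction with edge-reliability pruning, MCODE- and CMC-style
    graph clustering detectors, overlap-based merging and duplicate filtering,
    and clustering-wise evaluation (Sn, PPV, geometric accuracy, maximum
    matching ratio) against a reference complex catalogue. Ships a seeded
    synthetic-data generator that plants coupled biclusters and complexes so
    the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    generics,
    ggplot2,
    igraph,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
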