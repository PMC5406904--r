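Package: netpathad
Title: Network- and Pathway-Based Analysis of Disease Gene Sets
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A pipeline for the systems-level analysis of disease-associated
    gene lists: gene-set over-representation analysis (one-sided
    hypergeometric test with Benjamini-Hochberg adjustment), construction of
    pathway-crosstalk networks scored by Jaccard and overlap coefficients,
    compilation of protein-protein interaction networks from edge lists,
    inference of disease-specific subnetworks with a greedy Steiner minimal
    tree heuristic, and assessment of network non-randomness against
    Erdos-Renyi G(n,m) null ensembles.  Ships a transcription of a curated
    Alzheimer's disease pathway-enrichment table as a worked example, and
    synthetic-data generators so that every stage can be exercised and
    benchmarked without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
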