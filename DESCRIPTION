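Package: gammaSFC
Title: Multi-Scale Fusion of Structural and Functional Brain Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fuses population structural and functional brain connectivity
    matrices through a single interpolation parameter gamma, builds
    hierarchical module trees of the fused network by weighted agglomerative
    clustering on correlation distance, and selects the partition maximizing
    cross-modularity (the geometric mean of structural modularity, functional
    modularity and their module similarity) over the (gamma, module count)
    plane. Includes multi-scale dendrogram metrics (module size, multi-scale
    index, height), node-strength and module-segregation summaries, overlap
    annotation of partitions against reference atlas labelings, gene-set
    scoring of modules against brain-disorder gene panels, and a synthetic
    cohort generator with planted nested modules for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, ape, jsonlite
Suggests: testthat (>= 3.0.0), withr, igraph, mclust, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
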