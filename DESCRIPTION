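Package: panmap
Title: Multiscale Pangenome Graphs from Sparse Hierarchical Minimizers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds sparse hierarchical minimizer (SHIMMER) indexes over
    haplotype assembly sequences, retrieves homologous regions by anchor
    lookup with sparse chaining, constructs minimizer-anchored pangenome
    (MAP) graphs without base-level alignment, relinearizes tangled graphs
    into principal bundles projected onto each contig as BED intervals, and
    derives graph-level polymorphism (diffusion entropy) and repetitiveness
    metrics.  Ships a deterministic synthetic-pangenome generator with
    planted repeat, palindrome and inversion structure, SVG rendering of
    bundle decompositions, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    Matrix,
    Biostrings,
    ape,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    xml2,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
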