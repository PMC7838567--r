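Package: tsrkeys
Title: Alignment-Free Protein Structure Comparison with Triangular
    Spatial Relationship Keys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes every C-alpha triangle of a protein structure as an
    integer key from its ordered amino-acid labels, discretized longest
    edge (MaxDist) and discretized angle (Theta), represents structures
    as key-frequency vectors, and compares them with generalized Jaccard
    similarity. Includes adaptive unsupervised discretization for bin
    boundary fitting, class-level key-set algebra (common, specific and
    per-protein common keys with Venn counts), tolerant motif matching,
    mirror-image signed keys for chirality, secondary-structure
    restricted key generation (IASS/IESS), amino-acid grouping,
    synthetic C-alpha trace generators, and thin reproducible wrappers
    for clustering, embedding and Adjusted Rand Index scoring.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
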