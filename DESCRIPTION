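Package: polyquart
Title: Quartet-Frequency Polytomy Tests for Species Trees
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tests the null hypothesis that an internal branch of a
    phylogenetic species tree is a polytomy, using gene-tree quartet
    topology frequencies under the multi-species coalescent (MSC).
    For every internal branch the three unrooted quartet topologies
    around the branch are tallied across gene trees (with support for
    missing taxa and unresolved gene trees), and a chi-squared
    goodness-of-fit test against the equal-frequency null yields a
    per-branch p-value. Includes closed-form MSC quartet probabilities,
    power analysis (required number of genes per branch length),
    deviation models for skewed frequencies and gene flow, a coalescent
    gene-tree simulator operating in coalescent units, Yule species-tree
    generation, and a command-line interface for testing, collapsing
    non-rejected branches, and running simulation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape (>= 5.0),
    optparse,
    phangorn,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
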