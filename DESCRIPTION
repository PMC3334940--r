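Package: snpcombine
Title: Discriminative Pattern Mining of High-Order SNP-Genotype
    Combinations in Case-Control Studies
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mines high-order combinations of SNP genotypes associated
    with a binary phenotype using an Apriori search under the
    anti-monotone SupMaxPair objective.  Genotypes are expanded into a
    lossless three-column binary encoding so that the association test
    for a combination of any size is a 2x2 chi-square with one degree
    of freedom.  Provides jump-based filtering of combinations that are
    trivial extensions of their subsets, size-specific permutation
    false-discovery-rate estimation, gene-set search constraints, a
    Hardy-Weinberg case-control genotype simulator with embedded
    ground-truth patterns, and functional-coherence analysis of the
    gene pairs inside discovered combinations against a
    degree-preserving null.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
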