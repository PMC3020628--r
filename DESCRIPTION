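Package: kelpcoast
Title: Phylogeographic Connectivity Analysis for Coastal Kelp Populations
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Haplotype-based phylogeographic analysis for rocky-shore
    organisms sampled along an essentially one-dimensional coastline.
    Collapses aligned mitochondrial or chloroplast sequences to haplotypes,
    summarizes variable sites, computes raw pairwise-difference distances
    (Nei's raw average pairwise difference D) and uncorrected p-distances,
    tests isolation-by-distance with a Mantel permutation test, builds
    statistical-parsimony haplotype networks with a confidence-based
    connection limit, and models genetic disjunction between adjacent
    localities as a function of habitat discontinuity (maximum uninterrupted
    beach length) with Firth-penalized logistic regression. Includes a
    seeded synthetic-coast generator that plants a monomorphic southern
    clade, an isolation-by-distance gradient, and beach-length barriers, so
    the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
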