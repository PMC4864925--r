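Package: ptmsel
Title: Selection and Driver Analysis of Cancer Mutations in Lysine
    Acetylation and Ubiquitination Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for analysing somatic missense
    mutations that fall in or near lysine acetylation and ubiquitination
    sites. Maps 15-mer site sequences onto a proteome, builds merged
    +/-7-residue site regions, classifies mutations as direct, proximal
    or distal to modified lysines, and tests for positive selection with
    bootstrap resampling nulls. Includes a per-gene active-site driver
    test based on a per-residue Poisson null model with an exact upper
    tail, a mutation-frequency-binned permutation test for known cancer
    gene enrichment, gene-set enrichment with a Poisson exact test and
    enrichment-map export, and greedy discovery of survival-correlated
    protein interaction modules scored by the log-rank test and
    controlled by network-shuffling permutations. A seeded synthetic
    data generator with planted ground truth makes every stage testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    igraph,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
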