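Package: panmito
Title: mtDNA Control-Region Phylogeography: Haplogroup Classification,
    Median-Joining Networks and Coalescence Dating
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for maternal-lineage phylogeography from human
    mitochondrial DNA control-region data: parsing and serialising
    rCRS-relative variant notation (transitions, transversions,
    insertions, multi-base deletions, reversions, heteroplasmies),
    motif-based haplogroup classification on a user-supplied haplogroup
    tree, regional haplogroup frequency tables with chi-square tests of
    geographic structure, median-joining haplotype networks, coalescence
    dating by the rho statistic with its heuristic standard error and by
    maximum likelihood under HKY85 with discrete-gamma rate variation
    and partitioned rates, sequence diversity summaries (pi, k, Hd),
    pedigree-based deduplication of maternally related samples, and a
    seeded synthetic-cohort generator for end-to-end validation.
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
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    Matrix,
    optparse
Config/testthat/edition: 3
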