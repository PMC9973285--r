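Package: phylograft
Title: Taxonomy-Guided Phylogeny Expansion and Phylogeny-Aware
    Diversity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Grafts species identified by NCBI taxonomy IDs onto a rooted
    reference phylogeny using their taxonomic lineages, making the tree
    congruent with metagenomic classification output, and provides the
    downstream phylogeny-aware community analyses that such a tree
    enables: abundance-weighted Faith's phylogenetic diversity, weighted
    mean pairwise distance, weighted and unweighted UniFrac and
    Bray-Curtis dissimilarities, tip-shuffling null models for community
    dispersion, and PERMANOVA with either free or tip-shuffle
    permutation schemes. Includes parsers for NCBI taxdump files and
    Bracken/Kaiju abundance reports, community filtering and
    rarefaction, and a synthetic-data generator producing
    taxonomy-congruent trees and structured communities for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    methods,
    stats,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0),
    picante,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
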