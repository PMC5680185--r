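Package: orderphy
Title: Gene-Order Phylogenies and Probabilistic Ancestral Genome
    Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Whole-genome gene-order phylogenetics for multi-chromosome
    genomes with unequal gene content, duplications and rearrangements.
    Genomes are encoded as binary presence characters for gene content and
    gene adjacencies, evolved under an asymmetric two-state gain/loss model
    whose rates derive from double-cut-and-join (DCJ) event counts.
    Provides maximum-likelihood tree inference with nonparametric
    bootstrap, posterior reconstruction of ancestral gene content and
    adjacencies by Felsenstein pruning with per-ancestor re-rooting,
    assembly of ancestral chromosomes via a travelling-salesman heuristic
    with telomere priority rules, a genome rearrangement simulator, and
    evaluation metrics (reconstruction accuracy, non-split adjacencies,
    synteny blocks, dot-plot coordinates).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    Matrix
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
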