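Package: viridicore
Title: Comparative Genomics of Early Green Plant Evolution
Version: 1.0.0
Authors@R:
    person("Viridicore", "Developers", email = "viridicore@example.org",
           role = c("aut", "cre"))
Description: Reusable, tested implementations of the comparative-genomics
    procedures used to characterise deep-branching green algal genomes:
    k-mer spectrum genome-size estimation, orthogroup presence/absence set
    algebra with minimal-core-genome reconstruction, lineage-biased
    gene-family classification, Dollo parsimony gain/loss mapping of binary
    traits on species trees, reciprocal-best-hit protein inventories with a
    flagellate-capability classifier, phylogenomic supermatrix construction
    with gap-column masking, and tree-aware synapomorphy scanning.  Every
    input class can be simulated with known ground truth, so the whole
    pipeline is exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
LinkingTo: Rcpp
Config/testthat/edition: 3
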