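Package: syntrans
Title: Genomic Coordinate Translation Across Genomes via Synteny-Map Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Translates annotated genomic features (GTF) between genomes
    connected by a graph of pairwise synteny maps, without requiring
    all-to-all whole-genome alignments. Candidate loci are located by
    binary search over synteny anchors along a fixed shortest path of
    maps, refined by blockwise FFT cross-correlation search and banded
    gap-affine local alignment with binomial-tail significance, and
    classified against annotations native to the target genome
    (full/partial sense, intronic, antisense). Includes a deterministic
    genome-evolution simulator (substitutions, indels, inversions,
    tandem duplications) that emits genomes, exact synteny anchors,
    planted gene models and a ground-truth coordinate map for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    igraph,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    rtracklayer
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
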