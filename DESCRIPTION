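Package: taxalign
Type: Package
Title: Joint Taxonomic and Gene Assignment for Metatranscriptomic Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A nucleotide full-alignment engine for metatranscriptomic
    read classification. Reads are assigned to microbial species by
    FM-index seeding against a chunk-partitioned reference database
    followed by threshold-bounded semi-global alignment with per-taxon
    early stopping, and simultaneously to genes by querying the retained
    alignment coordinates against interval-indexed GFF3 annotations.
    Read-level assignments are aggregated into taxon-resolved gene and
    ortholog-group count matrices suitable for downstream differential
    expression tools. A synthetic community simulator with per-read
    truth labels supports end-to-end accuracy evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    withr,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
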