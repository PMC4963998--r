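Package: smartclassifier
Title: Sharded Exact-Match 30-mer Classification of Metagenomic Reads
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Taxonomic classification of shotgun metagenomic reads by exact
    30-mer matching against a prefix-sharded hashtable database. Reference
    genomes are tiled into non-overlapping 30-mers, each linked to a
    species/genus/class lineage, and split into 256 shards keyed by the
    first four bases. Reads are searched with a step-1 sliding window on
    both strands, optionally expanding every one-base substitution of each
    window to tolerate sequencing errors and SNPs. Per-read verdicts are
    obtained by vote tallying at each taxonomy level with tie-aware
    ambiguity handling and a conservative host (mammalian) override.
    Includes a self-contained community and read simulator with truth
    tracking, and sensitivity/precision evaluation against truth labels.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    data.table,
    jsonlite,
    withr,
    parallel,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
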