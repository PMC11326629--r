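Package: seqcollide
Title: Interspecies Sequence Collisions in Growing Marker-Gene Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies how species-level taxonomic resolution of marker-gene
    reference databases (16S rRNA and universal single-copy protein-coding
    genes) degrades as databases grow. Simulated databases are built by seeded
    random subsampling over a size grid, clustered with a greedy incremental
    identity clusterer that requires the shorter sequence to align fully to
    the longer one, and scored for interspecies sequence collisions
    (multi-species clusters). The super-linear growth of collisions with
    database size is estimated with a power-law regression in log-log space.
    A synthetic database generator with fully known taxonomy, planted
    verbatim cross-species collisions, and length artifacts makes the whole
    pipeline testable without reference-database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
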