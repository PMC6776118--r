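Package: magchar
Title: Comparative Characterization of Metagenome-Assembled Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative characterization of metagenome-assembled
    genomes (MAGs): average amino acid identity (AAI) from reciprocal
    best-hit orthologs using exact Smith-Waterman protein alignment with
    Karlin-Altschul E-values, taxonomic rank delineation from AAI bands,
    marker-based completeness/contamination estimation with MIMAG quality
    tiering, rule-based metabolic pathway presence calling, detection and
    synteny comparison of fumarate-addition-enzyme (faeDCAB) operons with
    transporter-gene insertions, protein motif scanning, and stoichiometric
    ATP/Gibbs-energy bookkeeping for fermentation pathways. Includes a
    synthetic genome simulator with controlled amino-acid divergence,
    marker dropout/duplication and planted operons for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
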