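Package: ampliscreen
Title: In-Silico Amplicon Similarity Screening of 16S rRNA Primer Pairs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: In-silico PCR and amplicon-similarity screening for prokaryotic
    16S rRNA primer pairs. Degenerate primers (IUPAC codes) are matched with
    zero mismatches against complete genomes on both strands, inter-primer
    segments are extracted as in-silico amplicons subject to length bounds,
    and all amplicons obtained with one primer pair are aligned all-vs-all
    with an exact semiglobal (full-query, free subject end-gaps) dynamic
    programming aligner using MegaBLAST-style scoring. Species pairs whose
    amplicons align with 100% query coverage and at least 97% identity are
    recorded as similarity relations, from which per-primer species-coverage
    statistics (SC, SC-ASI97, SC-NASI97), species-pair frequency tables,
    cross-rank tallies and networks of potential OTUs (connected components
    at the 97% threshold) are derived. A synthetic-community generator with
    planted primer sites and designed pairwise identities provides full
    ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    grDevices,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
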