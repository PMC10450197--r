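Package: plasmidnet
Title: Identification and Characterization of Plasmid-Like Sequences in
    Bacterial Draft Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for discovering plasmid-like sequences
    (PLSs) in draft genomes of bacterial isolates and characterizing them:
    strand-neutral MinHash sketching and Mash-style distance estimation, a
    labeled plasmid/chromosome fragment reference database, marker-gene
    frequency-ratio selection, two-stage PLS identification with phage
    screening and backbone-gene detection, complete-linkage clustering into
    plasmid-like clusters (PLCs), completeness estimation from direct
    terminal repeats and assembly graphs, similarity-network typing by
    Markov clustering, host-range / prevalence / persistence summaries, and
    median-joining haplotype networks with a linear transmission clock.
    Includes seeded synthetic-data generators that fabricate every input the
    pipeline consumes, with recorded ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
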