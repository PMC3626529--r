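Package: dbgasm
Title: Desk-Scale De Novo Short-Read Assembly with De Bruijn Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A fully testable short-read de novo assembler at desk scale:
    k-mer spectrum error correction (fast single-site and bounded deep
    multi-site search, with an optional spaced k-mer corroboration scheme),
    dense and sparse de Bruijn graph construction with tip clipping, bubble
    popping and low-coverage filtering, iterative multi-k contig assembly by
    read threading, hierarchical paired-end scaffolding with heterozygous
    contig-pair masking, chimeric-join rectification and topology-based
    recovery of weakly supported links, and iterative cross-cycle gap
    closing. Ships a seedable truth-known read simulator (haploid/diploid
    genomes, repeats, multiple insert-size libraries) and an assembly
    evaluator (N50/NG50, reference coverage, structural errors) so every
    algorithm is verifiable on synthetic genomes.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    data.table,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
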