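Package: anchormap
Title: Genetic-Map and Linked-Read Anchoring of Draft Assemblies into
    Pseudomolecules
Version: 0.1.0
Authors@R:
    person("anchormap", "developers", email = "anchormap@example.org",
           role = c("aut", "cre"))
Description: Builds chromosome-scale pseudomolecules from draft contigs by
    combining two sources of long-range evidence: barcode sharing between
    contig ends from linked-read (10x-style) sequencing, and linkage
    disequilibrium among genotyping-by-sequencing markers segregating in a
    biparental recombinant inbred line (RIL) population. Provides RIL
    genotype filtering, a two-state Viterbi HMM for parental haplotype
    assignment and imputation, breakpoint-based genetic distance
    estimation, LD-graph linkage-group inference, Salsa-style greedy
    scaffold-graph clustering, chimeric-contig detection and breaking,
    ordering and orientation of scaffolds by genetic position with AGP
    output, and recombination-landscape summaries (Marey profiles,
    sliding-window recombination rates, pericentromere calls). A
    synthetic-data module simulates inbred genomes, single-seed-descent
    RIL populations, fragmented contigs and barcoded molecules so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
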