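Package: ervkit
Title: Mining and Population Analysis of Murine Leukemia Virus-Type
    Endogenous Retrovirus U3 Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the in-silico characterization of murine leukemia
    virus-type endogenous retroviruses (MuLV-ERVs) from U3 promoter
    sequences. Provides a synthetic-data generator that plants proviruses
    with ground truth into random genomes and simulates U3 clone
    libraries; U3 clone deduplication, size-driven phylogenetic grouping,
    direct-repeat feature annotation and tropism calling; population
    diversity statistics (segregating sites, nucleotide diversity,
    Watterson's theta, Tajima's D) on progressive multiple alignments;
    IUPAC consensus-motif scanning of promoter sequences; U3-probe
    provirus mining with LTR pairing, primer-binding-site typing and
    gag/pol/env open-reading-frame integrity calls; neighbor-gene mapping
    within a flanking window including intronic-integration flagging; and
    densitometry fold-change and sorted-cell purity arithmetic.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
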