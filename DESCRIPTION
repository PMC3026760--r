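Package: virnatools
Title: Virus-Derived Small RNA Profiling and Annotation of Bipartite RNA Virus Genomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing natural RNA virus infections of
    Caenorhabditis nematodes from sequence data. Provides annotation of
    bipartite nodavirus-like genomes (ORF scanning, detection of overlapping
    +1-frame B2-like ORFs and of a second 3' ORF on the capsid segment),
    a small-RNA read-processing pipeline (barcode demultiplexing, trimming,
    collapsing to unique inserts), an exact unambiguous short-read mapper,
    per-position sense/antisense viRNA profiles with length by 5'-nucleotide
    signature matrices and a 22G-signature summary, neighbor-joining
    phylogenetics with bootstrap supports, Fisher's exact statistics for
    symptom scoring, and a fully seeded synthetic-data generator with truth
    records for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: Sequencing, SmallRNA, Annotation, Phylogenetics, Software
RoxygenNote: 7.3.3
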