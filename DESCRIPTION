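Package: numtforge
Title: Detection and Characterization of Nuclear Mitochondrial DNA Insertions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies nuclear copies of mitochondrial DNA (NUMTs) in
    assembled genomes with a built-in seed-and-extend local aligner using
    Karlin-Altschul E-value statistics, applies strict E-value and
    scaffold-end filters, and merges high-scoring segment pairs into NUMT
    loci. Characterizes the resulting loci by length spectrum,
    mitochondrial gene of origin, insertion-site nucleotide composition,
    and position relative to protein-coding genes, and screens
    transcriptomes for chimeric transcripts in which a NUMT is fused with
    its flanking nuclear sequence. A synthetic-data generator plants
    decayed mitogenome fragments with known ground truth into simulated
    AT-rich genomes so that every stage of the pipeline can be validated
    against planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
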