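Package: mitoforge
Title: Structural and Post-Transcriptional Analysis of Multipartite Plant Mitogenomes
Version: 0.1.0
Authors@R:
    person("Mitoforge", "Developers", email = "mitoforge@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing multipartite circular plant mitochondrial
    genomes: dispersed repeat and microsatellite (SSR) discovery, enumeration
    of repeat-mediated homologous recombination products (split, fusion,
    inversion), junction-model construction and classification of spanning
    long reads into major/minor genome configurations, C-to-U RNA editing
    site calling from read pileups with DNA-level SNP masking and codon
    consequence annotation, and detection of mitochondrion-plastid (MTPT)
    and mitochondrion-nuclear (NUMT) homologous segments. Includes a
    synthetic-data module that generates toy mitogenomes, configuration
    mixtures of long reads and editing pileups with planted truth, so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    Rsamtools,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    BiocGenerics,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
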