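Package: gusloci
Title: Sequence-Based Screening of Beta-Glucuronidase Loci in Gut Microbiomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens metagenomic contigs for beta-glucuronidase loci and the
    conserved C7D2 glucuronide transporter that discriminates Crohn's
    disease-related gut microbiomes from unrelated healthy ones. Provides a
    six-frame translated homology search with affine-gap Smith-Waterman
    alignment, a deterministic ORF caller, PROSITE-style motif matching and
    conserved-pattern induction, gene-neighborhood (synteny) classification of
    the GUS/C7D2-transporter/AFTR locus, neighbor-joining phylogenetics with
    identity-threshold clade grouping, cohort statistics (Fisher exact,
    chi-squared, Mann-Whitney, Bray-Curtis PCoA), and a fully ground-truthed
    synthetic cohort generator so that every stage is testable without access
    to the original microbiome databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    vegan,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
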