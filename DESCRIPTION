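Package: spacerscape
Title: Comparative Analysis of CRISPR-Cas Systems Across Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for comparative CRISPR-Cas genomics in multi-strain
    bacterial data sets, modelled on surveys of the marine actinomycete genus
    Salinispora. Detects repeat-spacer arrays de novo with a confirmed-only
    confidence filter and assembly-gap merging, classifies type I cas operon
    subtypes from annotated gene content, catalogues and deduplicates spacers
    across strains, matches spacers against prophages, mobile genetic element
    databases and the host chromosome using perfect (full-length, 100%
    identity) and partial (>= 18 nt exact) criteria, aligns homologous spacer
    arrays to expose clade-specific insertion/deletion blocks and SNP-bearing
    spacer variants, and evaluates biogeographic sharing with the standard
    nonparametric test battery. A synthetic-data generator plants every
    feature class with a full ground-truth manifest so each stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
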