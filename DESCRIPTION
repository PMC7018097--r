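Package: polespectra
Title: Mutational Spectrum and Regional Mutation-Rate Analysis for POLE-Mutant Cancer Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing hypermutated cancer genomes carrying
    mutations in the exonuclease (proofreading) domain of DNA polymerase
    epsilon (POLE). Builds trinucleotide (96-channel) and pentanucleotide
    (1536-channel) mutation spectra with genome context-frequency
    normalization, clusters samples by spectrum similarity, and fits
    non-negative signature contributions. Stratifies CpG sites by methylation
    level to relate 5-methylcytosine to C>T mutation burden, with
    pentanucleotide composition normalization of per-bin rates. Computes
    observed and context-expected mutation profiles around CTCF binding sites
    and transcription start sites, mutation density across gene parts,
    replication-strand mutational asymmetry and timing-binned densities, and
    nucleosome minor-groove periodicity of mutation rate. Detects recurrent
    driver hotspots and tests group enrichment with exact Fisher tests under
    Benjamini-Hochberg FDR control. A seeded synthetic-data generator emits
    genomes, methylation tracks, replication landscapes, gene models and
    signature-driven mutation cohorts with plantable effects so every stage
    is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    pracma,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
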