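Package: orfeome
Title: Alternative Open Reading Frame Annotation and Proteogenomic Databases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Enumerates every open reading frame of at least 30 codons in all
    three reading frames of every transcript of an annotated genome,
    irrespective of RNA biotype, and classifies the predicted proteins as
    reference proteins, novel isoforms (II_ accessions) or alternative
    proteins (IP_ accessions). Aggregates mass-spectrometry and ribosome
    profiling evidence with target-decoy FDR control and peptide-uniqueness
    mapping, calls intrinsically disordered regions and filters short linear
    motifs, bins structure-prediction confidence, annotates genomic variants
    across all (including frame-overlapping) ORFs of a transcript, and builds
    expression-ranked custom protein databases capped at a configurable size.
    Includes a deterministic synthetic mini-genome generator with recorded
    ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
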