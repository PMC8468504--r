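Package: AMPminer
Title: Motif-Anchored Mining and Physicochemical Profiling of
    Antimicrobial Peptide Precursors in Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mines transcriptome-derived open reading frames for
    antimicrobial peptide (AMP) precursors using signal-peptide motif
    anchors and family-diagnostic rules (piscidin-like, beta-defensin,
    hepcidin, LEAP-2, NK-lysin), derives candidate mature and truncated
    peptides at propeptide-convertase and monobasic cleavage sites, and
    computes the physicochemical and amphipathicity descriptors used to
    select synthesis candidates (average and monoisotopic mass, formal
    and pH-dependent net charge, isoelectric point, hydrophobic ratio,
    Fauchere-Pliska mean hydrophobicity, Eisenberg hydrophobic moment,
    helical-wheel face geometry). Includes a seeded synthetic
    transcriptome generator with ground truth so the whole pipeline is
    testable without sequencing data, plus in-silico tryptic digestion
    and FPKM utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
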