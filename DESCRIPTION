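Package: lncpep
Title: Discovery and Exploitation of lncRNA-Derived MHC Class I Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A proteogenomics pipeline for long non-coding RNA (lncRNA)
    derived MHC class I peptide discovery. Builds expression-gated
    target/decoy peptide search databases by three-frame translation of
    lncRNA transcripts binned on TPM; enumerates ATG-to-stop small open
    reading frames (smORFs); assigns provenance (canonical proteome versus
    lncRNA-derived) and source ORFs to mass-spectrometry-identified
    peptides; classifies lncRNA genes as direct or associated transcription
    factor targets from ChIP-seq peaks in 1000-bp TSS windows; designs
    poly-antigen vaccine cassettes with natural flanking sequence, a Kozak
    sequence and a tPA secretion leader, and ORF cloning amplicons; and
    ships a seeded synthetic-data generator with a ground-truth manifest so
    the whole pipeline is testable end-to-end without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
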