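Package: rcscreen
Title: Deep Mutational Scanning Analysis of Yeast Complementation Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for deep mutational scanning (DMS) screens that
    score single-nucleotide variants (SNVs) of a human open reading frame by
    complementation of a yeast loss-of-function mutant. Enumerates every
    possible SNV of an ORF with protein-level consequences and HGVS names,
    computes log2 depletion scores (complementation scores) from replicate
    before/after-selection sequencing count tables, classifies variants as
    damaging or tolerated with a logistic model trained on internal
    nonsense/synonymous controls, and compares calls against external
    annotations (clinical classes, other functional assays, variant effect
    predictors). Includes a seeded simulator of error-prone-PCR variant
    libraries, selection, and replicate count tables so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
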