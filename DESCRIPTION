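Package: epiedit
Title: Epitope-Editing Target Discovery and Validation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for discovering and validating epitope-editing
    targets on cell-surface receptors. Provides combinatorial and
    degenerate-codon mutagenesis library design, sorted-fraction
    sequencing analysis (variant counting, positional amino-acid
    frequency logos, single- vs double-positive enrichment), base-editor
    sgRNA nomination with bystander outcome prediction, amplicon editing
    quantification, bias-reduced (Firth-penalized) binomial logistic
    regression for off-target calls, GUIDE-seq site filtering and
    annotation, transcriptome A-to-G editing-rate summaries,
    four-parameter log-logistic antibody affinity-curve fitting with
    likelihood-ratio comparisons, and synthetic-data generators for
    every input so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    rtracklayer
Config/testthat/edition: 3
RoxygenNote: 7.3.3
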