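Package: oocyteDecay
Title: Maternal mRNA Half-Life and Codon Optimality Analysis for the
    Oocyte GV-to-MII Transition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates per-transcript mRNA half-lives from two-timepoint
    poly(A) RNA-seq of transcriptionally quiescent oocytes (germinal
    vesicle to metaphase II), using mean normalization and decay-factor
    normalization to correct the compositional inflation caused by global
    mRNA loss, followed by linearized exponential-decay fitting. Compares
    half-lives between reproductively young and aged groups with a
    standard-score test and Bonferroni correction, extracts CDS/UTR
    sequence features (GC/AU content, IUPAC S/W codon-class fractions,
    codon frequencies, Kozak context score), computes binned codon
    stability coefficients (CSC) and the protein abundance codon
    correlation (PACC), and ships a ground-truth-known synthetic data
    generator so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    SummarizedExperiment,
    S4Vectors,
    jsonlite
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
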