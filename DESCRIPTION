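Package: beadwell
Title: Bead-Barcoded Microwell Single-Cell RNA-Seq: Simulation, Demultiplexing and Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for bead-barcoded microwell single-cell RNA-seq without
    unique molecular identifiers. Models the random 12-nt bead barcode library
    (collision statistics) and Poisson cell loading into microwells
    (singlet/multiplet rates), simulates barcoded paired-end reads with known
    ground truth, demultiplexes cell barcodes with optional whitelist error
    correction, assigns reads to genes (built-in exact-substring aligner or an
    external SAM alignment stream), builds digital expression matrices with
    cell QC and per-cell tag normalization, performs species-mixing (barnyard)
    analysis, classifies cells by marker rules including an
    epithelial/intermediate/mesenchymal trichotomy of tumour cells, tabulates
    positive-cell counts and fold ratios between two tissue sides, and provides
    the accompanying statistics (Mann-Whitney U with exact enumeration,
    Benjamini-Hochberg FDR, log-scale Pearson correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings,
    S4Vectors,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
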