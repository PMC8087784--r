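Package: methylink
Title: Integrative Methylome, Transcriptome and Small RNA Analysis of
    Seasonal Cambium Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, simulation-validated pipeline linking
    whole-genome bisulfite sequencing methylomes, RNA-Seq expression and
    small-RNA profiles across developmental stages of woody-plant
    vascular cambium (dormant, reactivating, active). Implements
    binomial methylation-site calling with Benjamini-Hochberg control,
    per-context (CG/CHG/CHH) global, windowed and metagene methylation
    statistics, Fisher-exact differentially methylated region (DMR)
    detection and gene annotation, a negative-binomial exact test for
    differential gene and miRNA expression, k-means expression
    patterning, miRNA-target correlation analysis, and
    methylation-expression integration. A companion synthetic-data
    module generates methylomes, count matrices and miRNA/target pairs
    with machine-readable ground truth for calibration and power
    checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    DESeq2,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
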