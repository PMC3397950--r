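Package: cervmeth
Title: DNA Methylation Biomarker Discovery and Evaluation for Cervical
    Neoplasia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for promoter-methylation biomarker discovery
    and pre-validation. Implements MeDIP tiling-array enrichment calling
    (Tukey biweight centering of probe log2 ratios, sliding-window one-sided
    Kolmogorov-Smirnov scoring, thresholded region calling and promoter
    annotation), multi-evidence candidate-gene triage, methylation-index
    (M-index) quantification of quantitative methylation-specific PCR data
    with a reference-gene validity rule, and ROC-based diagnostic evaluation
    across cervical-neoplasia grades (Kruskal-Wallis and Mann-Whitney tests,
    bootstrap median intervals, AUC with DeLong intervals, Youden cutoff
    selection, Wilson intervals, and power at a cutoff). Seeded synthetic
    generators for grouped tiling-probe sets with planted hypermethylated
    promoters and for grade-structured QMSP cohorts make every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
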