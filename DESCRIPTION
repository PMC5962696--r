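Package: taascreen
Title: In Silico Tumor-Associated Antigen Screening for Whole-Cell Immunotherapy Lines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Expression-based antigen discovery for GM-CSF-secreting whole-cell
    immunotherapy candidates. Reads and merges probe-by-sample expression
    matrices (TSV and GCT dialects), applies RNA-integrity and variability
    quality gates, quantile-normalizes intensities and derives a background
    cutoff for expressed-gene calling, collapses samples into per-group
    representative values, and runs three screens: an Immune-Signature screen
    over immunostimulatory genes, a cancer/testis-antigen overexpression
    screen against non-cultured normal breast cells, and a serial three-tier
    tumor-associated-antigen filter with a calibrated breast-cancer versus
    normal-tissue verification quotient. Also provides an nCounter-style
    digital-count normalizer and an HLA phenotype-frequency calculator, plus
    a synthetic-study generator with planted ground truth for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
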