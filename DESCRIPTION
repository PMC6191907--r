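Package: rifadecay
Title: Genome-Wide mRNA Half-Life Estimation from Rifampicin-Chase
    Two-Color Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates bacterial mRNA half-lives from rifampicin-chase
    two-color microarray experiments: spike-in based normalization of
    GenePix-style spot tables, quality filtering, replicate averaging,
    per-gene log-linear decay fits with an R-squared gate and a
    three-point fallback window, operon-level aggregation, functional
    category statistics (one-way ANOVA, post-hoc t-tests with Bonferroni
    correction), FPKM quantification from fragment counts, and
    coverage-based detection of rRNA fragmentation regions from
    full-length high-identity read mapping. Ships synthetic-data
    generators that emulate every input with known ground truth.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
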