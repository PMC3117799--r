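Package: mircalib
Title: Calibrating Circulating miRNA Signatures for Hematopoietic Cell
    Contamination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Separates bona fide circulating microRNA signal from
    hematopoietic-cell contamination in fractionated blood plasma measured
    on probe-level microarrays. Provides GC-stratified background
    correction against anti-genomic probes, Wilcoxon rank-sum detection
    calls, quantile normalization and median probe-set summarization;
    contaminant cataloguing from red-blood-cell, white-blood-cell and
    leukocyte fractions; intensity-stratified Spearman concordance,
    replicate-stability and coefficient-of-variation analyses; a
    permutation-based SAM (significance analysis of microarrays)
    implementation with delta/FDR thresholding and q-values; and a
    synthetic fractionation and cohort simulator so every stage is
    verifiable without array downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    limma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
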