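Package: waveCNA
Title: Absolute Copy Number and LOH from Noisy Tumor SNP-Array Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: De-convolutes absolute somatic copy number, tumor genotype and
    loss of heterozygosity from noisy Affymetrix-style tumor SNP-array signals
    (Log R Ratio and B allele frequency in PennCNV layout). LRR tracks are
    de-noised by a sym8 wavelet decomposition with per-level SURE soft
    thresholding; copy-number and genotype states are decoded by a hidden
    Markov model whose emissions account for normal-cell contamination, LRR
    baseline shift, GC waviness, signal fluctuation outliers and a
    copy-number-specific homozygous-BAF variance, with all parameters fitted
    by expectation-maximization. Across multiple tumors, recurrent
    amplification, deletion and LOH are scored by an exact convolution-based
    significance test with Benjamini-Hochberg FDR control. A synthetic-data
    generator with the same statistical structure supports testing and
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
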