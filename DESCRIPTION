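Package: hafkit
Title: Haplotype-Derived Allele Frequencies for Evolve-and-Resequence Pool-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates pooled allele frequencies from ultra-low-coverage
    pool-seq data by inferring founder-haplotype frequencies in overlapping,
    recombination-scaled genomic windows and summing founder alleles weighted
    by those frequencies (haplotype-derived allele frequencies, HAFs).
    Includes an EM estimator of window haplotype frequencies from aligned
    reads, the effective-coverage accuracy metric, a forward-in-time
    recombination and selection simulator with an exact-truth pooled read
    simulator, and a log-linear model to predict effective coverage from
    window read counts and missing-genotype rates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    Matrix,
    data.table,
    jsonlite,
    Rcpp,
    IRanges,
    S4Vectors,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
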