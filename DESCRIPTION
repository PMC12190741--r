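Package: sexchrombench
Title: Simulation Benchmark for Alignment and Variant Calling on the Sex Chromosomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulation study of how alignment, genotype-calling
    ploidy, and hard-filter choices affect variant detection on the human X and
    Y chromosomes. Generates toy X/Y reference pairs with pseudoautosomal
    (PAR), X-transposed (XTR), and ampliconic region architecture, simulates
    cohorts of XX/XY individuals with golden SNP truth sets and paired-end
    reads, prepares default and sex-chromosome-complement (hard-masked)
    references, maps reads with an ambiguity-aware ungapped mapper, performs
    ploidy-aware joint genotyping with GATK-style site annotations, applies
    hard filters and depth/allele-number threshold sweeps, and scores calls
    against the golden truth per sample, region class, and 50-kb window.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    Biostrings,
    IRanges,
    vcfR,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    S4Vectors
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
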