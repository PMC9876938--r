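Package: GenoPhase
Title: Benchmarking Genotype-Array Data Integration for Haplotype Phasing and
    Imputation on Synthetic Biobanks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating how protocols for integrating cohorts
    genotyped on different arrays affect haplotype phasing and whole-genome
    imputation, and downstream complex-trait analyses. Provides a seedable
    synthetic-biobank generator (haplotype panel with linkage disequilibrium,
    population structure and admixture, array manifests with partial overlap,
    genotyping waves, parent-offspring trios, heritable quantitative traits),
    a pre-phasing quality-control battery (missingness, differential
    missingness, Hardy-Weinberg, order-statistic batch-artifact FDR,
    ancestry-adjusted heterozygosity, Mahalanobis outlier detection,
    relatedness), four data-integration protocols (separate, intersection,
    union, two-stage), a desk-scale Li-Stephens haplotype-copying engine for
    phasing and dosage imputation with a DR2-style quality metric, and
    evaluation of trio switch error rates, imputation r2 by minor-allele
    frequency bin and ancestry group, genomic-control inflation of
    array-membership association scans, and polygenic-score attenuation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
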