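Package: fscollapse
Title: Data-Adaptive Forward-Selection Collapsing Tests for
    Quantitative-Trait Association with Rare and Common Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Gene-level association testing between quantitative traits and
    mixed common/rare genetic variants.  Implements a data-adaptive forward
    selection strategy that seeds each gene with its most significant common
    SNP and greedily accretes rare variants into a collapsed burden score
    (indicator, sum, or Madsen-Browning weighted-sum collapsing), a
    genome-wide permutation test that normalises the selection-biased
    statistics per gene and yields family-wise global p-values via the
    max-statistic distribution, the non-selective baseline burden tests
    (T_ind, T_sum, T_ws, T_com) with Bonferroni correction, covariate
    selection and principal-component adjustment of phenotypes, and a
    simulation harness for type-I-error and power evaluation on synthetic
    genotype/phenotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
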