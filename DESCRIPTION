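Package: mbpqtl
Title: Multiple-Trait QTL Detection by Maximum Bootstrap Power
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Multiple-trait quantitative trait locus (QTL) mapping for
    recombinant inbred line populations using multivariate-normal
    likelihood-ratio genome scans. Trivial QTL effects are excluded by
    backward elimination, and the number of nontrivial effects at each
    scanning locus is chosen by maximum bootstrap power (MBP): the effect
    count whose best-k statistic exceeds its permutation-based genome-wide
    threshold in the largest proportion of nonparametric bootstrap samples.
    Comparator procedures (joint test of all effects, individual-effect
    tests, sequential elimination, and BIC with a permutation-calibrated
    penalty), follow-up tests of individual QTL-trait associations with
    Bonferroni correction over the selected effects, delete-1 jackknife
    relative frequencies, and Monte Carlo calibration studies are included,
    together with a synthetic data generator for RIL genotypes and
    correlated multivariate-normal traits.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
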