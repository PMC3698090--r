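Package: ramltest
Title: Rare Admixture Maximum Likelihood Test for Rare-Variant Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Region-based association testing of rare genetic variants with
    dichotomous or quantitative phenotypes using the rare admixture maximum
    likelihood (RAML) test. Per-variant evidence is summarised as signed
    score-test z-statistics under a covariate-only null model, variants in
    strong linkage disequilibrium are collapsed to proxy variants by
    single-link clustering on squared correlation, and the z-statistics are
    modelled as a two-component mixture in which each variant is associated
    with probability alpha and associated effects are normally distributed
    with mean eta and standard deviation sigma. The maximised mixture
    log-likelihood is the test statistic; significance is assessed by
    phenotype permutation. Includes a haplotype-pool disease simulator and a
    power-evaluation harness for case-control designs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minqa,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
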