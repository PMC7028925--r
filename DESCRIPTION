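Package: hybridgate
Title: Detection and Management Classification of Wild x Domestic Admixture
    from Multilocus Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A standardized workflow for detecting and classifying
    wild x domestic admixture (e.g. wolf x dog hybridization) from
    multilocus codominant genotypes such as microsatellites. Provides
    simulation of synthetic reference populations with controlled
    differentiation, Mendelian simulation of hybrid classes (F1, F2 and
    successive backcrosses), injection of allelic dropout and missing
    data, a K=2 Bayesian admixture-model Gibbs sampler with one-by-one
    query assignment and 90% credibility intervals, a genotype-frequency
    class sampler over five hybrid classes, an empirical q-threshold
    performance analysis (efficiency x accuracy), three-way management
    classification with type I/II error accounting, and integration of
    uniparental and diagnostic-locus evidence.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
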