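Package: admixstep
Title: Supervised Ancestry Estimation with Bootstrap Denoising and Stepwise Reference Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Two-step estimation of the fraction of an individual's genome
    derived from each of K continental ancestral populations. A supervised
    maximum-likelihood admixture model is fit by EM against a labeled
    reference panel; moving-block bootstrap standard errors are then used to
    drop populations without statistically significant contributions before a
    refining second supervised pass ("denoising"). Also provides the stepwise
    reference-panel construction algorithm (unsupervised seeding of
    well-differentiated groups followed by anchored supervised expansion with
    threshold admission), marker and sample quality control, a validation
    battery (identity-by-state distances, principal coordinate analysis,
    Hudson Fst, permutation distance-variance testing, leave-one-out
    resampling, standard-error versus marker-count curves, trio consistency),
    and a Balding-Nichols simulator so the whole pipeline is testable without
    external genotype resources.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    vcfR,
    vegan,
    yaml,
    optparse
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
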