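Package: qtlseries
Title: Bayesian Inference of the Allelic Series at QTL in Multiparental Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the allelic series -- the partition of founder haplotypes
    into functionally distinct alleles -- at a quantitative trait locus in
    multiparental populations. Implements a Bayesian hierarchical model with a
    Chinese restaurant process prior over haplotype partitions, an exact
    tree-informed prior derived from functional mutations on a coalescent
    phylogeny with the mutation rate marginalized analytically, a collapsed
    multivariate-t likelihood over diplotype states, a partially collapsed
    Gibbs sampler, Chib-style marginal likelihood estimation for Bayes factor
    comparison against haplotype-based and null models, and a coalescent
    simulation protocol for method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
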