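Package: famvarsim
Title: Simulation of Genetic Variants in Unrelated Individuals and Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates realistic genetic-variant data from a phased VCF panel.
    Haplotypes are modelled as thresholded multivariate Gaussians so that both the
    allele-frequency spectrum and the short- and long-range linkage-disequilibrium
    structure of the input population are preserved in simulated unrelated
    individuals. Pedigrees of arbitrary size are generated by gene dropping with
    explicit recombination (a chi-squared crossover-interference model with an
    escape pathway, or a no-interference Poisson model) and exact segment-based
    identity-by-descent tracking. Includes phenotype generators (logistic
    case-control and Weibull correlated-frailty survival models) and a
    likelihood-ratio association test for the frailty variance with the boundary
    mixture chi-squared null, together with a replicated power/type-I-error study
    driver and a synthetic-fixture generator for fully self-contained runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    survival,
    utils,
    vcfR
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    mvtnorm,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
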