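Package: polydose
Title: Bayesian SNP Dosage Calling for Polyploids by Exact MAP Inference
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Genotype (allele dosage) calling from two-channel SNP allele
    intensities for individuals of arbitrary, possibly unknown, ploidy.
    Models the full population jointly: a Gaussian likelihood on the
    L1-normalized intensity ratio couples with a multinomial probability of
    the genotype count distribution under Hardy-Weinberg, F1 segregation
    (hypergeometric gametes), or user-supplied genotype frequency models.
    The maximum a posteriori genotype configuration, ploidy, cluster
    standard deviation and model parameters are found exactly by a
    geometric branch-and-bound over genotype count distributions, with
    greedy, naive-enumeration and dynamic-programming engines available for
    comparison. Includes a generative simulator, posterior approximation
    with a user-set error bound, per-individual genotype posteriors, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
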