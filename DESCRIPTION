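Package: kernelpred
Title: Kernel and Neural-Network Genomic Prediction for Multi-Environment Testcross Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for head-to-head comparison of multi-kernel reproducing
    kernel Hilbert space (RKHS) regression and feed-forward neural networks
    on genomic prediction problems. Includes a synthetic multi-environment
    testcross data generator with additive, dominance, epistatic,
    genotype-by-environment and environmental variance components; additive
    and dominance marker codings, principal-component predictors and
    mixed-model GWAS marker selection; linear, Gaussian and arc-cosine
    kernels with composite weather kernels and Hadamard-product interaction
    kernels; marginal-likelihood kernel hyperparameter optimization; a
    Gibbs sampler for multi-kernel Bayesian variance-component models in
    the kernel eigenbasis; a compact dense/convolutional network engine
    with a replicated tuning and epoch-selection protocol; and evaluation
    under a five-problem taxonomy of prediction targets with
    replicate-aware Dunnett comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    multcomp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
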