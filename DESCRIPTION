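Package: tfode
Title: Bayesian Inference of Combinatorial Transcription Factor Regulation
    from Expression Time Series
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers which of a small set of transcription factors (TFs)
    regulate each gene from short, noisy gene expression time series. A
    training phase uses Markov chain Monte Carlo over ordinary differential
    equation models of transcription and translation, with Gaussian process
    priors on the TF mRNA functions, to infer latent TF protein activities
    on a subnetwork of approximately known structure. A prediction phase
    scores every candidate combination of regulators for each gene by a
    fast annealed-importance-sampling approximation to the Bayesian
    model evidence and
    reports posterior probabilities of network links by Bayesian model
    averaging. Includes maximum-likelihood and regression baselines, a
    synthetic benchmark generator with a deliberately unmodelled
    confounding TF, and ROC, enrichment and bootstrap evaluation
    utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    parallel,
    S4Vectors,
    SummarizedExperiment,
    pROC
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
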