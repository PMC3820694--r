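Package: refens
Title: Bayesian Inference of Conformational Ensembles from Sparse Averaged
    Restraints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers conformational ensembles of flexible biomolecules from
    sparse, noisy, ensemble-averaged distance restraints. A hierarchical
    Bayesian model treats the observed data as noisy observations of an
    auxiliary ensemble average and is combined with a fine-grained
    conformational prior through the reference-ratio (Kullback-Leibler
    optimal) modification. Includes joint Metropolis-Hastings sampling over
    conformations and ensemble averages without discrete replicas,
    Monte-Carlo estimation of the reference distribution, empirical-Bayes
    estimation of the per-restraint scale vector, reductions to inferential
    structure determination and maximum-entropy restraining, a minimal
    C-alpha trace polymer prior, synthetic-data generation with constant
    signal-to-noise, ensemble evaluation statistics, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
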