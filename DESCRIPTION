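Package: gradres
Title: Graduality of Acquired Drug Resistance: Lattice Simulation and
    Statistical Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative machinery for deciding whether acquired drug
    resistance arises through a single (epi)mutational hit or through
    gradual multi-step adaptation. Provides a stochastic agent-based model
    of colony growth on a 2D culture-dish lattice with evolving division
    probability, calibration of division probabilities from observed
    colony sizes, Kullback-Leibler divergence model selection over a
    (mutation probability x step number) parameter grid, a bootstrap
    Kolmogorov-Smirnov test of the tolerant/resistant mixture null,
    limiting-dilution estimation of resistance-initiating cell frequency
    with delta-method errors, four-parameter logistic dose-response
    fitting, and lentiviral barcode clone-tracing analysis (enrichment
    calling, Shannon diversity, replicate correlation, hierarchical
    clustering). A synthetic-data generator emulates every input so the
    full pipeline runs and is tested without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
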