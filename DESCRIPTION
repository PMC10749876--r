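Package: ctxcode
Title: Long-Lasting Sensory Context Effects in Auditory Cortical Populations
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to design balanced context-probe natural-sound sequences by
    exact cover, simulate trial-based auditory cortical population recordings
    with known ground-truth context effects, quantify per-instance context
    effects with a cluster-mass permutation test and integral-amplitude /
    last-bin-duration metrics, characterize the sparse population code for
    sensory context (contextual coverage, site union, best neuron, first
    principal component), impose a matched dense code and compare linear
    decoding of context and probe identity, run category-level and cell-type
    statistics, and fit rectified-linear encoding models with self- and
    population-history terms to test circuit mechanisms of contextual
    integration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    e1071
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Electrophysiology, Software, StatisticalMethod
RoxygenNote: 7.3.3
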