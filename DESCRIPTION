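Package: crpeeg
Title: Concept Relevance Propagation for Convolutional EEG Decoders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Interpretability toolkit for compact convolutional EEG decoders
    (EEGNet-style networks). Implements layer-wise relevance propagation
    (LRP) with the epsilon/alpha-beta composite, concept relevance
    propagation (CRP) conditioned on individual filters, a discrete-Fourier
    virtual inspection layer that projects relevance into the frequency
    domain, relevance maximization for selecting concept-representative
    samples, UMAP+DBSCAN clustering of filter concepts across
    subject-independent models, topographic band maps, functional grouping
    of scalp regions, ICA-based artifact relevance projection, and a
    cross-model consistency statistic. Ships a multi-subject synthetic EEG
    generator with planted spatial/spectral class signatures and artifact
    sources so the whole pipeline can be validated against ground truth,
    plus the preprocessing chain (notch, band-pass, resampling, common
    average reference, batch standardization) and subject-independent
    leave-one-out training of the network.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    signal,
    uwot,
    ica,
    clue,
    rhdf5,
    digest,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
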