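Package: dreamcatcher
Title: Blinded Unsupervised Classification of Dreamful and Dreamless
    Sleep Polysomnograms
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for running a fully blinded, step-wise classification of
    1-minute non-REM sleep polysomnogram segments as dreamful or dreamless.
    Implements hypothesis-driven EEG/EOG/EMG feature extraction (Welch power
    spectra, band powers, permutation and approximate entropy,
    autocorrelation and RMS summaries), temporal-consistency screening of
    candidate feature sets, a silhouette-weighted co-association ensemble
    ("combination clustering") over random feature combinations,
    pair-difference mean-orientation and hyperplane sub-clustering for
    paired designs, per-participant ICA cleanup, literature-derived spectral
    labeling rules, and exact binomial / Monte-Carlo power evaluation of the
    resulting calls. A synthetic polysomnogram generator reproduces the
    9-participant x 3-session x 2-condition (54-case) blinded cohort design
    with tunable participant random effects and condition band-power
    effects, together with EDF and blinding-key input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    cluster,
    jsonlite,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Clustering, FeatureExtraction, TimeCourse, Classification
RoxygenNote: 7.3.3
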