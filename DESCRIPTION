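Package: eegFatigueNet
Title: Band Power, wPLI Connectivity and Graph-Theory Analysis of Pre/Post
    Cognitive-Fatigue EEG
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for paired (pre/post task)
    resting-state EEG studies of cognitive fatigue. Provides Welch power
    spectral density estimation with band-power extraction for the theta,
    alpha and beta bands; weighted phase lag index (wPLI) functional
    connectivity matrices from Hilbert instantaneous phase; proportional
    thresholding and weighted graph-theory metrics (global and local
    efficiency, clustering coefficient, characteristic path length,
    small-world sigma, nodal efficiency and degree centrality) with
    region-level aggregation on a 56-channel 10-20 montage; a paired
    statistics layer with normality gating, Cohen's d and Wilcoxon effect
    sizes, Bonferroni families and Spearman correlation against subjective
    fatigue scores; and a seeded synthetic-cohort generator with known
    band-power and phase-coupling ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    igraph,
    jsonlite,
    nortest
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'montage.R'
    'dsp-utils.R'
    'synthetic.R'
    'spectral.R'
    'connectivity.R'
    'graph-metrics.R'
    'stats.R'
    'pipeline.R'
    'io.R'
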