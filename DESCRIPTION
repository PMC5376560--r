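Package: masticNet
Title: Mastication-Related Resting-State Functional Connectivity Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying the association between masticatory
    performance and resting-state functional connectivity. Implements a
    synthetic BOLD-like cohort generator with planted ground truth, ROI
    time-series preprocessing (initial-volume discard, linear detrending,
    ideal 0.01-0.08 Hz bandpass filtering, nuisance regression), head-motion
    quality control, construction of weighted 24-node connectivity networks
    from absolute Fisher r-to-z edge weights, degree-centrality hub
    identification, and covariate-adjusted brain-behavior statistics
    (partial correlation controlling age and gender, edge screening,
    median-split demographics).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    RNifti
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
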