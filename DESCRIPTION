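Package: dfcstream
Title: Dynamic Functional Connectivity Streams, Speeds, Scaling and
    Meta-Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Characterizes the dynamics of functional connectivity (dFC)
    estimated from multivariate neural time-series (fMRI BOLD, LFP, EEG or
    any real-valued signals) as a complex random walk in the space of
    functional networks, without extracting discrete connectivity states.
    Provides sliding-window dFC streams with a canonical link vectorization,
    recurrence (dFC) matrices, global and network-restricted dFC speed
    distributions with Agresti-Coull confidence intervals, detrended
    fluctuation analysis of instantaneous dFC increments, meta-connectivity
    (inter-link covariance) with trimer meta-strengths and signed-Louvain
    dFC modules, edge-centric FC, stationarity-preserving phase-randomized
    and frame-shuffled surrogate nulls, and seedable synthetic generators
    (stationary and covariance-switching Gaussian series, planted
    covarying-link modules, fractional Gaussian noise).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
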