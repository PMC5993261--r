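Package: dfcstates
Title: Dynamic Functional Connectivity States and Network Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sliding-window dynamic functional connectivity analysis for
    node (component) time courses: time-course preparation (initial-volume
    discard, detrending, zero-phase low-pass filtering, spectral quality
    control), windowed correlation and L1-regularized sparse precision
    estimation, exemplar-initialized k-means clustering of windows into
    recurring connectivity states with occupancy-based model selection,
    per-subject state metrics (frequency, dwell time, transitions), static
    and state-level graph metrics (clustering coefficient, average shortest
    path length, global efficiency, strength, distance-weighted network
    cost, hub identification), and group-level statistics including
    test-retest reliability. Includes a hidden-Markov switching-covariance
    cohort simulator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    MASS,
    signal,
    igraph,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
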