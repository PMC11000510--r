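Package: multidfc
Title: Multi-Method Dynamic Functional Connectivity Estimation and Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates dynamic functional connectivity (dFC) from parcellated
    BOLD time series using seven widely used methods (tapered sliding-window
    correlation, wavelet transform coherence, coactivation patterns,
    sliding-window clustering, continuous and discrete hidden Markov models,
    and window-less k-SVD dictionary learning), standardizes their outputs
    into a common labeled (subject, method, time, ROI, ROI) array, and
    quantifies the agreement between methods with a comparison framework:
    overall, spatial, temporal, and intersubject similarity under several
    metrics, Ward hierarchical grouping of methods, variance decomposition of
    dFC over method, time, and subject, and a time-shuffled permutation null.
    Includes a Markov-switching Gaussian BOLD simulator with planted
    connectivity states used as ground truth for validating every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
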