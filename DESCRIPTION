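Package: wavecch
Title: Frequency-Resolved Functional Connectivity from Spike-Train
    Cross-Correlograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers functional connectivity between simultaneously recorded
    neurons by applying a complex Morlet continuous wavelet transform to
    pairwise spike-train cross-correlation histograms. Wavelet power peaks
    are tested against Monte-Carlo significance thresholds calibrated on
    Poisson white-noise correlograms, classified into frequency bands
    (high-frequency, gamma, beta, theta) and into delayed (directed) versus
    non-delayed connections, and assembled into density-controlled binary
    networks. Includes subsampling-controlled graph measures (degree
    distributions, clustering, efficiency, assortativity), model degree
    distributions (binomial, exponential, subsampled scale-free), an
    exponential distance-decay fit of connection probability, and a
    synthetic spike-population generator with known ground-truth couplings
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    minpack.lm,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
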