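Package: mesn
Title: Modular Echo State Networks for EEG Band-Power Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds echo state networks whose reservoir is initialized to a
    brain-inspired modular (community-structured) topology controlled by the
    module count M and the intra- and inter-module connection probabilities
    P1 and P2. Provides the leaky-integrator reservoir dynamics with a
    ridge-regression readout, an EEG relative band-power feature pipeline
    (theta/alpha/beta/gamma), a memory-capacity evaluator for reservoirs,
    degree-distribution heterogeneity statistics, a grid-search protocol over
    the modularity parameters with repeated k-fold cross-validation, and a
    synthetic EEG generator with class-dependent sub-band power so the whole
    pipeline can be exercised without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
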