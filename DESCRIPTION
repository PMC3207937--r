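Package: allosense
Title: Sensing Characteristics and Trade-Offs of Allosteric MWC Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing populations of two-state allosteric
    (Monod-Wyman-Changeux) sensors such as bacterial allosteric
    transcription factors. Computes six sensing characteristics from
    biochemical parameters - dynamic range, Hill number, intrinsic noise,
    information-transfer capacity, static gain and response time -
    together with the optimal input/output distributions for information
    transfer and the linearized frequency response. Validates the
    binomial intrinsic-noise model by exact stochastic simulation
    (Gillespie direct method, compiled core) with a finite input pool,
    and provides ensemble-level analytics over log-uniform parameter
    samples: characteristic-space occupancy, pairwise normalized mutual
    information, the analytic forbidden-region boundary in
    Hill-number/dynamic-range space, and the two-topology response-time
    comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
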