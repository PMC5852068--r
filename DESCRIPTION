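Package: epifield
Title: Epileptor Neural Field Modelling of Seizure Propagation and Termination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Simulation and analysis of the Epileptor neural field model of
    focal seizure dynamics: a slow-fast integro-differential field on a
    periodic one-dimensional domain with local (Laplacian-kernel) and
    long-range (Gaussian-kernel) coupling, integrated by a compiled RK4/FFT
    scheme. Includes semi-analytic wave-speed methods (a shooting method in
    the co-moving frame for the slow ictal wavefront and a
    relaxation-oscillator quadrature for fast spike-and-wave discharges),
    seizure-termination analysis (onset/offset detection, pre-offset
    pairwise correlation, mean-shift clustering of termination delays),
    connectome-based contact-pair features, synthetic fixture generators for
    intracranial recordings and connectomes, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
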