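Package: nfsom
Title: Neural-Field Self-Organizing Maps and Their Stability Conditions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a self-organizing map driven by an Amari-type neural
    field with difference-of-Gaussians lateral connectivity and an Oja-like
    feed-forward learning rule, as used to model topographic map formation in
    primary somatosensory cortex (area 3b). Provides forward-Euler integration
    of the coupled field/learning dynamics with a compiled inner loop,
    Picard solution of the equilibrium field pattern, closed-form and
    quadrature evaluation of the Lyapunov-derived exponential-stability
    conditions on the lateral kernel, and map-quality metrics (quantization
    distortion, the delta-x/delta-y topology representation and its scalar
    performance index). Includes reproducible experiment drivers for the
    stable regime, the unstable regime and amplitude sweeps, plus a small
    command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
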