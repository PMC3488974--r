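Package: aruopt
Title: Adaptive Stochastic Search for Multi-Drug Combination Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Closed-loop stochastic search over discrete multi-drug
    concentration grids. Implements the adaptive reference update (ARU)
    algorithm together with the Gur Game finite-state-automaton baseline
    (simultaneous and sequential update strategies) and an informed-guess
    single-drug adaptive baseline; a library of analytic benchmark response
    surfaces (Rosenbrock saddle and multi-drug trigonometric/Gaussian test
    functions); an evaluation oracle with additive uniform measurement noise
    and cached (type-A) or re-measuring (type-B) revisit semantics; and a
    seeded Monte-Carlo harness reporting success rates and the number of
    unique drug combinations tested. Trials run through a compiled engine
    with a bit-identical reference implementation in R.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
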