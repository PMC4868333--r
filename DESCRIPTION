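Package: pulsechase
Title: Pulse-Length-Aware Analysis of Macromolecule Decay Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits pulse-chase and pulse-only decay patterns of macromolecules
    (mRNA, proteins) with a two-stage Markov lifetime model whose absorption
    time is a phase-type distribution. Provides closed-form decay curves that
    include the pulse duration explicitly, bounded multistart least-squares
    estimation of the three transition rates from one or several decay
    patterns, model selection against the one-stage (exponential) model,
    derived stability quantities (mean lifetime, half-time, state occupancies,
    steady-state abundance), local parameter sensitivities for the pulse-only
    design, and a stochastic single-molecule simulator used as an independent
    oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
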