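Package: ampnoise
Title: Feedback-Loop Placement and Gene-Expression Noise in Insect Immune
    Signaling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Stochastic and deterministic models of Imd- and Toll-like innate
    immune signaling circuits, used to ask how the cellular location of
    negative feedback loops (receptor-level Pirk versus nuclear Repressosome or
    Cactus) shapes noise in antimicrobial-peptide (AMP) expression. Provides a
    discrete-time two-reaction-set stochastic simulator with periodic pathogen
    encounters, a stiff-ODE counterpart, coefficient-of-variation noise
    summaries over replicate ensembles, average-matched noise comparisons,
    positive-feedback slope analyses, and greedy hill-climbing evolutionary
    simulations of the circuit parameters under a bacterial-load plus
    immunopathology fitness function.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
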