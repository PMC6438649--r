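Package: valleycross
Title: Fitness-Valley Crossing by Elitist and Non-Elitist Stochastic Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs long k-path fitness landscapes containing tunable
    fitness valleys and chains of consecutive valleys, simulates the (1+1)
    evolutionary algorithm, the strong-selection weak-mutation (SSWM)
    process driven by Kimura's fixation probability, and the Metropolis
    algorithm on them, and computes exact crossing times and peak-to-peak
    drift through Gambler's-Ruin closed forms with self-loops and
    absorbing-Markov-chain linear solves. Includes reproducible scaling
    experiments contrasting the elitist runtime law (exponential in the
    effective valley length) with the non-elitist law (exponential in the
    valley depth).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
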