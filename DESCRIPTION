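Package: beliefgame
Title: Evidential Naming-Game Dynamics on Social Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based naming-game model of language dynamics in which each
    individual on a social network holds a Dempster-Shafer belief function over
    the regular and irregular forms of a set of verbs, and updates it through
    weighted evidential-reasoning social learning with degree-based weights and
    similarity-based reliability discounting, preference-biased self-learning,
    and memory-constrained forgetting. Provides generators for the network
    families used in the study (Watts-Strogatz, Erdos-Renyi, Barabasi-Albert,
    a tunable-heterogeneity interpolation, an LFR-style community benchmark,
    and the Zachary karate-club fixture), a compiled simulation core, and the
    convergence, consensus, and regularization observables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
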