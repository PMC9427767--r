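Package: phonosynth
Title: Minimum-Description-Length Induction of Morpho-Phonological Grammars
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Induces ordered SPE-style context-dependent rewrite rules and a
    concatenative lexicon from small paradigm matrices of form/meaning pairs,
    selecting the grammar that minimises total description length subject to
    exactly reproducing the data. Provides an exact bounded-search backend and
    a counterexample-driven incremental backend, Pareto-frontier enumeration of
    the parsimony/fit trade-off, allophony (underlying-form directionality)
    solving, few-shot artificial-grammar-learning simulation with held-out
    Bayesian scoring, and fragment-grammar metatheory induction across
    problems. Includes binary feature systems, CV syllabification, a seeded
    synthetic-problem generator for parameter-recovery experiments, and
    ggplot2 visualisations of Pareto fronts and discrimination scores.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
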