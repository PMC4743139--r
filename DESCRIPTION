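Package: oxyreq
Title: Naive Bayesian Prediction of Bacterial Oxygen Requirement from
    Pfam Domain Profiles
Version: 0.1.0
Authors@R:
    person("Oxyreq", "Developers", email = "oxyreq@example.org",
           role = c("aut", "cre"))
Description: Predicts the oxygen requirement class of a bacterial genome
    (aerobe, anaerobe or facultative anaerobe) from the presence or absence
    of Pfam-A protein domains, using Bernoulli naive Bayesian inference.
    Class-associated domains are selected by an in-class presence threshold
    combined with a two-tailed independent t-test, and predictions are made
    either in a single three-class step or through a two-step nested
    dichotomy that first separates respiration-capable genomes from
    anaerobes. Includes leave-one-out cross-validation with per-fold
    feature selection, one-vs-rest Matthews Correlation Coefficient
    evaluation, a parser for hmmscan tabular output, a synthetic
    presence/absence matrix generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
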