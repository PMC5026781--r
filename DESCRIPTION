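Package: indelhist
Title: Ab Initio Alignment Probabilities Under a General Insertion/Deletion
    Markov Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the general continuous-time Markov model of sequence
    evolution via insertions and deletions. Sequences are tracked by ancestry
    indices so that every indel history is a well-defined series of operators;
    the package provides the operator algebra with its binary equivalence
    relations and local-history-set (LHS) equivalence classes, exact
    hypoexponential path integrals for fixed histories, truncated perturbation
    expansions of pairwise- and multiple-alignment probabilities, the
    factorized (generalized-HMM-like) computation valid under locality
    conditions on the rates and exit rates, numeric checkers for those
    conditions, and a Gillespie simulator of the same model for
    cross-validation and fixture generation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
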