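Package: hmmtutor
Title: Discrete Hidden Markov Models with Step-by-Step Educational Reports
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A teaching-oriented toolkit for discrete first-order Hidden
    Markov Models: model specification and validation, seeded random
    parameter generation, Forward, Backward and Viterbi inference in plain
    and log-space modes, posterior decoding, a brute-force path-enumeration
    oracle for verification, and step-by-step derivation reports in plain
    text, Markdown or HTML. Ships a transmembrane-topology worked example
    (a 100-residue fragment of the 5-hydroxytryptamine receptor 2A, with
    synthetic surrogate parameters) and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    graphics,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
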