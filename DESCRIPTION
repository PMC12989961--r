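Package: gsvdnmf
Title: Rank Expansion for Nonnegative Matrix Factorization via the
    Generalized Singular Value Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Augments an under-complete nonnegative matrix factorization
    (NMF) with additional components by comparing it against the truncated
    singular value decomposition of the data through a generalized singular
    value decomposition (GSVD) of the projected pair, then refines the
    augmented factorization with standard NMF. Provides HALS and
    multiplicative-update solvers, NNDSVD-family initialization, a one-shot
    GSVD-based feature-recovery step with nonnegative least-squares
    amplitude rebalancing, an end-to-end rank-expansion pipeline with an
    incremental one-component-at-a-time mode, a seeded synthetic-data
    generator for smooth nonnegative sources, matrix and factorization I/O
    (delimited text and Matrix Market), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
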