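Package: tatkit
Title: Transferability Assessment for Linear Density Functional Approximations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing and embedding transferability in data-driven
    density functional approximations (DFAs) built as linear combinations of
    precomputed energy components. Implements a nested seven-parameter
    double-hybrid family, exact mean-absolute-deviation (least absolute
    deviations) training via linear programming, cross-set transferability
    and transfer-energy matrices, accuracy limits and error-class summaries,
    genetic-algorithm curation of compact training benchmark sets with an
    element-diversity bias, and a seeded synthetic benchmark generator with
    planted parameter vectors for end-to-end testing without quantum-chemistry
    inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    quantreg,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
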