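Package: creepfit
Title: Non-Linear Creep Models for Large-Deformation Viscoelastic Testing
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Fits constant-stress creep curves from large-deformation
    (non-linear viscoelastic) compression tests on soft biomaterials such as
    cooked rice. Implements a three-parameter power-law creep model alongside
    the classical Peleg and Purkayastha models, a Gauss-Newton least-squares
    solver with step-halving and parameter scaling, goodness-of-fit
    statistics, replicate aggregation with Duncan's multiple range test, a
    seeded synthetic creep-curve generator, and delimited-text input/output
    with force-to-stress and deformation-to-strain preprocessing, plus a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    minpack.lm,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
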