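Package: polystack
Title: Stacking Polytypes, Twin Laws and Diffraction from Faulted
    Molecular Layer Crystals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing polytypism and planar (stacking-fault)
    disorder in hydrogen-bonded molecular layer crystals such as the
    purine nucleobases.  Provides a four-vector interlayer stacking
    algebra with builders for ordered polytypes and randomly faulted
    supercells, recovery and classification of interlayer translation
    vectors from atomic models, twin-law determination from orientation
    matrices, kinematic diffraction (structure factors, systematic-absence
    checks, continuous reciprocal-space rod profiles with a
    Hendricks-Teller transfer-matrix oracle, and powder patterns), and
    Rietveld-style profile comparison (Rwp, Rexp, goodness of fit) between
    ordered and faulted models.  Includes a synthetic-data generator for
    planar molecules, layer motifs and Poisson-noised powder patterns so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
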