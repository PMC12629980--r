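Package: dendrodate
Title: Crossdating and Dendrochronological Dating of Wooden Art Objects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for tree-ring dating of boards from panel paintings and
    other wooden artefacts: reading and writing ring-width series in the
    Tucson (RWL), Heidelberg (FH) and plain CSV formats; crossdating by the
    Baillie-Pilcher t-statistic and the percentage of parallel variation
    (Gleichlaeufigkeit) with its significance; same-tree assessment of board
    pairs; localization and correction of single missing or doubled ring
    measurement errors; estimation of felling-date intervals and termini post
    quem from regional sapwood statistics, and of production windows under
    seasoning allowances; a seeded synthetic ring-width generator for method
    validation; and a dating-report renderer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
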