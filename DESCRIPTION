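Package: lifecor
Title: Lifespan-Correlation Screening of Multi-Tissue Strain Omics Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Screens strain-by-feature omics matrices (transcript or
    peptide abundances) for features whose expression correlates with
    strain median lifespan across a recombinant-inbred panel such as the
    BXD family. Implements extreme-strain (tails) selection, per-feature
    Pearson longevity scoring with slope and threshold vetting,
    cross-dataset overlap and shared-gene presence ranking,
    hypergeometric gene-set over-representation, and a synthetic panel
    generator with planted lifespan-correlated genes for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
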