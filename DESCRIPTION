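Package: qispr
Title: Quantified In Situ Pattern Analysis of Radial Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies in situ hybridization (ISH) signal across the embryonic
    cerebral wall as 20-bin radial optical-density profiles (quantified in situ
    patterns, QISPs), screens log2-scale RMA microarray matrices for fold-change
    regulated genes against a control-derived "not expressed" threshold,
    validates profiles with a deep-ratio criterion, clusters them hierarchically
    with a scale-invariant Pearson correlation distance, and assigns clusters to
    deep (ventricular zone), middle (intermediate zone) and upper (cortical
    plate) compartments. Includes a synthetic-data generator that renders ISH
    images and expression matrices with known ground truth so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    withr,
    png,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
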