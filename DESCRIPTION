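Package: busrep
Title: Semi-Automatic Structured Breast Ultrasound Report Synthesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based classification of breast ultrasound scan modes
    (B-mode, Doppler, shear-wave and strain elastography) from burned-in
    visual features, extraction and stiffness classification of shear-wave
    elastography regions of interest with a class-weighted pluggable
    classifier, recognition of burned-in operator annotations with
    context-weighted character-confusion correction, clock-face location
    parsing, location-based scan grouping, and compilation of templated
    structured findings reports. Ships a synthetic scan generator with
    embedded ground truth so the whole pipeline is testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    tibble,
    tidyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    png,
    nnet,
    withr,
    utils,
    stats,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
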