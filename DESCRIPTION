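Package: conascreen
Title: On-Bead Confocal Nanoscanning Screening of RNA-Protein Interaction Modulators
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies fluorescent rings on the periphery of agarose beads in
    two-channel confocal images of on-bead RNA pull-down (RP-CONA) assays,
    computes per-bead bound-protein/RNA ring-intensity ratios, aggregates them
    to wells, performs screening-plate quality control (Z' factor, coefficients
    of variation), calls interaction-inhibitor hits by mean - 3 SD and k x CV
    rules, and fits four-parameter logistic concentration-response curves for
    IC50 estimation. Includes a seeded synthetic bead-field and screening-plate
    generator with full ground truth so the whole pipeline can be validated
    without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    tiff,
    EBImage,
    minpack.lm,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
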