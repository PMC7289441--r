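Package: coprecip
Title: Stringent AP-MS Interactor Calling and Imaginal Disc Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for GFP-TRAP affinity-purification mass
    spectrometry (AP-MS) interactor calling against an accumulated
    negative-control false-positive database, with top-3 peptide quantification
    (T3PQ) abundance ranking; quantification of Drosophila eye-antennal imaginal
    disc z-stacks (maximum-intensity projection, disc segmentation, Elav area
    fraction, Caspase-3 focus calling with a 3x-basal threshold and a 1-60 um2
    area gate, and 2-SD disc-size classification); categorical eye-size
    phenotype tabulation with the conservative ambiguous-class tie-break; and
    seeded synthetic-data generators (spike-in AP-MS tables with ground truth,
    three-channel disc stacks with planted apoptotic foci) so that every stage
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
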