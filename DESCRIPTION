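Package: nanoladder
Title: Design, Simulation and Decoding of Ratiometric Fluorescent
    Nanoladders for Multiplexed RNA Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for in situ transcript imaging with RNA-primed rolling
    circle amplification (RCA) and branched-DNA ratiometric barcodes.
    Designs circular DNAzyme probes against target RNAs (cleavage-site
    finding, recognition arms, reference region, control variants,
    specificity screening), builds virtual-channel codebooks in which the
    repeat count of a detection fluorescent probe per amplicon unit encodes
    transcript identity, simulates single-cell ground truth and amplicon
    photometry including multi-channel image stacks, calls and colocalizes
    spots, decodes detection/reference intensity ratios back to transcript
    identities, and quantifies per-cell expression with detection-efficiency
    and 2^-ddCt estimators plus a nearest-centroid cell-type classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    readr,
    stats,
    tiff,
    Biostrings,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
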