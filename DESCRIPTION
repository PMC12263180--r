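Package: spherostain
Title: Quantification of Immunostain Penetration into Matrix-Embedded Spheroids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Image-quantification pipeline for immunofluorescence staining of
    multicellular spheroids embedded in thick hydrogel matrices. Measures the
    half-maximum radial penetration depth of a stain from radial line profiles,
    computes background-corrected mean intensity and total normalized intensity
    per spheroid and channel, fits staining-time courses by ordinary least
    squares, performs variance-gated two-group comparisons (F-test gate between
    Student's and Welch's t-test), and encodes staining-protocol schedules for
    total processing-time accounting. Includes a synthetic confocal image
    generator (blue-noise cell packing, four stain channels, radial staining
    front, Gaussian PSF blur, Poisson-Gaussian noise) with known ground truth
    so the whole pipeline is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
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
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
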