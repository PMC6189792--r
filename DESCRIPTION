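Package: cytocycle
Title: Image Cytometry of Cell-Cycle DNA Content for Adherent Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies cell-cycle phase distributions of spread (adherent)
    cells from single-channel fluorescence microscopy of DNA-stained nuclei,
    as performed in situ in microfluidic culture channels. Segments nuclei,
    subtracts background, integrates per-nucleus intensity as a DNA-content
    proxy, builds fixed-interval DNA-content histograms, places manual or
    automatic G1/S/G2-M gates, and reports phase fractions with replicate
    statistics and one-way ANOVA. Includes a seeded synthetic-microscope
    generator (2N-4N mixtures, staining saturation, detector clipping, CCD
    noise, nucleus clumping) providing ground truth for validation, plus
    acquisition quality control for over- and under-exposure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
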