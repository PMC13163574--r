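Package: cineflow
Title: Dynamic Intracardiac Blood-Flow Analysis from Cine Image Loops
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies intracardiac blood-flow behaviour from ECG-gated
    grayscale cine loops (intracardiac echo, TEE/TTE, MRI, angiography) by
    dynamic frame subtraction inside a user-delineated region of interest,
    five-band isophote segmentation of the differential grayscale, and two
    image-derived surrogate markers: the turbulence index (boundary
    irregularity of moving blood pools) and the blood mobility fraction
    (percentage of the region occupied by large coherently moving
    components at a pixel-area cutoff). Includes multi-frame DICOM and
    image-stack readers with embedded-ECG support, R-peak detection and
    cardiac-cycle averaging, cohort-level group statistics with an exact
    Mann-Whitney test, a synthetic speckle-phantom generator with ground
    truth for validation, colour-coded visualisation, and digital export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite,
    igraph,
    signal,
    png,
    tiff,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
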