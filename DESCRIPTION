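Package: spinesag
Title: Spinal Sagittal Parameter Measurement from Anatomical Landmarks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Measures the twelve regional and global sagittal alignment
    parameters of the spine (pelvic incidence, pelvic tilt, sacral slope,
    the L1/T1/C2 incidence angles of the inflection points, and six derived
    test parameters) from eleven anatomical landmarks on lateral whole-spine
    radiographs.  Includes a synthetic phantom generator that constructs
    landmark sets and radiograph-like images from target parameters, a
    decentralized coarse-to-fine landmark-detection cascade trained with a
    mean-absolute-error loss, and the agreement statistics used to validate
    such measurements (success-rate curves, Bland-Altman limits of
    agreement, ICC(2,1)).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
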