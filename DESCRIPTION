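Package: saxsqc
Title: Quality Control and Sample Logistics for Automated Solution Scattering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools supporting automated, mail-in biomolecular small-angle
    X-ray scattering (SAXS). Implements a longest-run ("coin toss")
    similarity statistic with exact null p-values for comparing scattering
    profiles, beam-center verification from the centro-symmetry of low-angle
    scattering, water-peak based buffer matching with an automated iterative
    estimator for the buffer-subtraction scaling factor, and the sample
    logistics layer for mail-in measurements: validation of measurement and
    96-well plate spreadsheets, plate-to-holder transfer-protocol generation,
    liquid-handler deck planning, and holder-manifest compilation. A
    synthetic-data generator produces scattering profiles, 2-D detector
    patterns and spreadsheets with planted ground truth so every component is
    testable without beamline data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    patchwork,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
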