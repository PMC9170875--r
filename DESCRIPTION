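Package: phenokit
Title: Canopy Trait Extraction from RGB, Depth and Thermal Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-based extraction of wheat canopy phenotypes as acquired in a
    gantry-equipped climate chamber: green index and reference-disk-calibrated
    leaf area from RGB images, plant height from registered depth images,
    canopy temperature statistics from calibrated thermal images, plus the
    agreement statistics (Pearson r, linear calibration fit, R-squared, RMSE)
    used to validate systematic against manual measurements. Includes a
    ground-truth synthetic scene generator for all three modalities and a
    serpentine cruise-path planner for the acquisition gantry.
License: MIT
Encoding: UTF-8
Imports:
    png,
    tiff,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
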