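Package: tsfitge
Title: Thermal Stability Shift Analysis of Multi-Channel 2D Gel Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of thermal stability shift fluorescence
    difference gel electrophoresis (TS-FITGE) experiments for proteome-wide
    drug target identification. Ingests per-temperature three-channel 2D gel
    images (Cy2 internal standard, Cy3 vehicle, Cy5 drug), detects and
    quantifies protein spots, computes Cy5/Cy3 ratio distributions and
    candidate rankings, matches spots across a temperature series, fits
    logistic melting curves normalized by the Cy2 internal standard, scores
    drug-induced melting-temperature shifts and longitudinal curve
    deviations, discriminates post-translational-modification spot pairs and
    channel misregistration artifacts from genuine thermal shifts, and fits
    isothermal dose-response curves. Includes a seeded synthetic gel-image
    generator providing ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    graphics,
    jsonlite,
    minpack.lm,
    png,
    pracma,
    rlang,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
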