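Package: olivescan
Title: Olive Fruit Image Analysis for Virgin Olive Oil Quality Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts virgin olive oil quality parameters (acidity index,
    peroxide value, UV absorbances, ethyl esters, polyphenols and pigments)
    from RGB images of olive batches photographed on a white tray.  Images
    are segmented by global thresholding, a 23-element feature vector is
    extracted per batch (9 colour-channel means over RGB, HSV and CIELAB
    plus the 14 Haralick grey-level co-occurrence texture descriptors), and
    per-parameter partial least squares (PLS1, NIPALS) regressions are
    calibrated and validated by repeated 50/50 holdout with a latent-variable
    sweep.  A synthetic-data module generates tray scenes and matched
    chemistry tables with the ripeness- and spoilage-driven structure the
    analysis assumes, so the whole pipeline runs and is tested without any
    external dataset.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
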