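Package: ccnni
Title: Canopy Cover Extraction and Nitrogen Nutrition Index Estimation for
    Winter Wheat
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates winter-wheat canopy cover (CC) from nadir RGB images
    by thresholding the per-pixel green-minus-red (G-R) colour index, fits
    allometric power-law models linking CC to growth indices (shoot dry
    matter, leaf area index, shoot nitrogen accumulation and concentration),
    tests whether per-group regressions can be pooled with a
    coincidence-of-regressions F test, and estimates the Nitrogen Nutrition
    Index (NNI) from CC by a direct fit or by closed-form composition of
    stage-wise power laws with a critical nitrogen dilution curve. Includes
    a synthetic-data module that generates canopy images with known
    ground-truth cover and multi-site factorial trial tables, so the whole
    pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    png,
    jpeg,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
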