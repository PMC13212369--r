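Package: fhocgrowth
Title: Femoral Head Ossification Center Morphometry and Growth Charts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Landmark-based size measurement of the femoral head ossification
    center (FHOC) from binary segmentation masks, the agreement and evaluation
    statistics used to validate automated pediatric hip measurements (Lin's
    concordance, Bland-Altman limits of agreement, Dice, Hausdorff, mean radial
    error, successful detection rates), and monotone-constrained polynomial
    quantile-regression growth charts with percentile reference tables. A
    synthetic-data module generates masks with analytic ground truth and
    measurement cohorts anchored to published percentile references, so the
    whole pipeline is testable without access to radiographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    png,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
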