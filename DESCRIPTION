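Package: lesionquant
Title: Patch-Based Lesion Quantification for Whole-Slide Liver Histology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated quantification of lesion burden in whole-slide liver
    histology images. Tissue regions are segmented by Otsu thresholding with
    morphological cleanup, a patch-wise classifier assigns each sliding-window
    tile a lesion probability, overlapping probabilities are accumulated into a
    per-pixel likelihood map, and the map is thresholded to yield the lesion
    area and the lesion-to-tissue area ratio. Includes a synthetic H&E-like
    slide generator with planted ground truth for end-to-end validation,
    cohort simulation for two-arm designs, and the group statistics (incidence,
    pooled t, chi-square, Fisher exact, one-way ANOVA) used to compare
    treatment arms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    tiff,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
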