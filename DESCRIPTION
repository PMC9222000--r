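Package: nucmorph
Title: Nuclear Morphometry and Discriminant Scoring for Prostate Cancer Grading
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative nuclear morphometry of segmented brightfield
    histology images and for grade discrimination in prostate adenocarcinoma. The
    package generates synthetic fields of labeled nuclei with grade-specific size,
    boundary-roughness and chromatin-intensity structure; extracts a 38-descriptor
    battery of size, shape, intensity and chromatin-texture features per nucleus
    (including box-counting fractal dimension of the boundary, integrated optical
    density, margination, heterogeneity and clumpiness); screens features with
    one-way ANOVA and Bonferroni pairwise tests across Gleason grade groups; and
    fits and applies a linear discriminant score with forward stepwise
    (Wilks' lambda) variable selection and ROC-based optimal-cutoff classification
    of low-grade (Gleason pattern 3 and below) versus high-grade (pattern 4-5)
    disease.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    EBImage,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
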