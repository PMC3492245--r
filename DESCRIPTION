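Package: herbgrade
Title: Colorimetric Quality Grading of Herbal Medicines
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Color-based quality grading of herbal medicines, demonstrated
    on rhubarb. Quantifies herb color as RGB triples, grades samples by
    total hydroxyanthraquinone content, trains a three-layer
    back-propagation neural network to predict the quality grade from
    color, converts colors to CIE 1931 xy chromaticity, and constructs a
    standardized colorimetric grading scale (per-grade expectation points,
    division point, angular sector classification) that can be rendered as
    a printable comparison card. Includes the 34-sample reference dataset,
    measurement-reproducibility statistics, and a seeded synthetic-data
    generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    stats,
    utils
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
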