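Package: circdet
Title: Circular Bounding-Box Machinery for Round-Fruit Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Geometry, post-processing and evaluation machinery for object
    detectors that localize near-spherical fruit with circular bounding
    boxes instead of rectangles. Provides exact circle-circle overlap area
    and intersection-over-union, greedy non-maximum suppression over
    circular or rectangular detections, k-means anchor clustering under an
    IoU distance, grid-cell prediction decoding and the associated
    detection loss, recall/precision/F1 and interpolated average-precision
    evaluation with a paired Wilcoxon sub-dataset comparison protocol, a
    synthetic scene generator for end-to-end testing without field images,
    a declarative validator for densely connected detection backbones, and
    annotation file input/output with a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
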