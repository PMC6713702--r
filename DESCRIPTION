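Package: orgadetect
Title: Tiled Detection and Morphometry of Organoids in Brightfield Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Localizes and quantifies spherical organoids in large brightfield
    microscopy images by sliding-window tiled detection. Plans an integer
    tiling with bottom/right zero-padding, runs a pluggable per-patch detector
    (a classical band-pass blob detector is included; a trained network can be
    plugged in through the same contract), rejects detections at interior tile
    edges, aggregates tile-local boxes into image-global detections by greedy
    non-maximum suppression, and converts each bounding box into physical-unit
    size measurements under an inscribed-ellipse assumption. Also implements
    the companion dataset workflow: the bounding-box annotation CSV schema,
    patchification of large images for annotation, multi-annotator consensus
    aggregation with agreement-based escalation, a recall-style mean average
    precision evaluated at 0.7 intersection-over-union, and a seeded synthetic
    brightfield scene generator with exact ground truth for end-to-end
    verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
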