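Package: scosfire
Title: Trainable S-COSFIRE Filters for Shape Detection in Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trainable hierarchical shape detection with COSFIRE
    (Combination Of Shifted FIlter REsponses) filters.  A three-layer
    model inspired by the ventral stream of visual cortex: a bank of
    Gabor energy filters detects oriented contour segments, vertex-
    selective V-COSFIRE filters combine Gabor responses to detect
    corners of given orientation and aperture, and shape-selective
    S-COSFIRE filters combine vertex responses arranged around a
    point of interest.  A filter is configured automatically from a
    single prototype image and responds, at every pixel, to spatial
    arrangements of contour vertices similar to the prototype, with
    tolerance to position, rotation, scale and reflection.  Includes
    a deterministic synthetic-stimulus generator (vertices, triangles,
    Kanizsa-style illusory triangles, partial and scrambled shapes),
    filter serialization and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
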