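Package: polarfuse
Title: Rotation-Robust Image Classification via Polar Feature Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies single-object images (e.g. plankton regions of
    interest) robustly to in-plane rotation by resampling each image into
    polar and log-polar coordinates, where rotation becomes a horizontal
    circular shift and isotropic scaling a vertical shift. Feature vectors
    tapped from the first fully connected layer of small convolutional
    networks trained on the Cartesian and polar views are spliced and
    classified with a one-vs-rest soft-margin support vector machine.
    Includes a synthetic plankton-silhouette generator, deterministic
    rotation/flip augmentation, and a four-method comparison harness
    reporting per-class precision, recall, accuracy and timing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    e1071,
    png,
    tiff,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
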