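Package: romval
Title: Validation of Markerless 3D Pose Estimation for Joint Range of Motion
Version: 0.1.0
Authors@R: person("Motion Analysis", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Tools to validate joint range-of-motion (ROM) measurements
    obtained from monocular 3D human-pose-estimation skeletons against
    optical motion-capture ground truth, for musculoskeletal
    telerehabilitation exercises. Provides a camera-invariant anatomical
    coordinate-frame construction from torso landmarks (RANSAC frontal-plane
    fit), per-exercise joint amplitude computation by in-plane projection
    against a reference direction, multi-rate temporal alignment of the two
    acquisition streams with peak-based fine tuning, exercise repetition
    segmentation, and an agreement-metric report (MAE, MAPE, Pearson r,
    cosine similarity, linear regression). A forward-kinematic synthetic
    motion generator produces paired acquisitions with known ground truth so
    that every pipeline stage is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
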