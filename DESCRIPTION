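Package: facsgraph
Title: FACS-Based Graph Features for Single-Frame Micro-Expression Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometric feature extraction for micro-expression recognition from
    68-point facial landmarks. Builds Action-Unit segment graphs grounded in the
    Facial Action Coding System (FACS), including per-emotion graphs and the
    combined deduplicated FACS graph (1178 segments) alongside the full-face
    one-to-all graph (2278 segments); computes Euclidean distance and slope
    (gradient) features per segment; restructures labelled landmark video
    sequences into single-frame samples via mid-frame, mid-three and mid-half
    sampling; and evaluates a support-vector-machine classifier under
    leave-one-subject-out cross-validation with accuracy and F1 reporting.
    Includes a synthetic landmark-sequence generator with AU-consistent
    deformations so the full pipeline is testable without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
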