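Package: retinotort
Title: Retinal Vessel Tortuosity Metrics and Multi-Expert Validation Workbench
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Measures retinal vascular tortuosity from fundus-style images
    and vessel centerlines using four reference metrics (arc-to-chord ratio,
    constant-sign-curvature subdivision, integrated curvature, and chain-code
    curvature), with arc-length-weighted integration over the vascular tree.
    Includes a vessel extraction pipeline (multiscale ridge detection,
    thinning, segment tracing), multi-rater agreement analytics (Cohen's
    kappa, majority-vote consensus, consensus percentages), ROC-based
    prognostic validation of continuous scores against binary consensus
    labels, and synthetic generators for vessels, rendered phantoms with
    ground-truth centerlines, and multi-rater ordinal rating panels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    pROC,
    e1071,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
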