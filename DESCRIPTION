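Package: kinemark
Title: Marker-Less Motion Biomarkers from Joint-Centre Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes clinically interpretable movement biomarkers from 3D
    joint-centre trajectories of squat and sit-to-stand actions, such as those
    produced by marker-less (RGB video) motion-capture front ends. Planar
    triplet joint angles are extracted per frame, repeats are aggregated into
    frame-wise mean/minimum/maximum curves without time normalisation, and per
    curve the gradient-SD smoothness and the cumulative absolute rotational
    acceleration are computed. Representative biomarkers are selected by
    cross-participant frequency of two-component PCA feature importances, and
    pre/post-intervention change is assessed with paired t-tests, Bland-Altman
    limits of agreement, and percentage-change summaries, assembled into an
    automatic clinical report. A synthetic motion simulator with known
    ground-truth angle curves supports validation end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
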