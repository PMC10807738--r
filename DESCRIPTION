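Package: kneemorph
Title: Automated Morphometry of Knee Radiographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated measurement of osteoarthritis-related morphometry on
    posteroanterior knee radiographs from a 99-point bone-contour landmark
    annotation. Builds a four-line measurement framework from supporting
    (tangent) lines of the annotated contours, fits 30 intra-articular
    inscribed circles to obtain mean medial/lateral and minimal joint space
    width, computes the joint line convergence angle and tibial eminence
    heights, and calibrates subchondral bone intensity in millimetres of
    aluminium equivalence against a step-wedge phantom. Includes the
    agreement statistics used to evaluate such measurements (two-way
    absolute-agreement intraclass correlation with F-based confidence
    intervals, Bland-Altman limits of agreement, mean absolute error) and a
    synthetic phantom generator with closed-form ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
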