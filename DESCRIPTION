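Package: cardiotwist
Title: Chamber Rotation and Twisting of the Embryonic Heart Tube from 3D
    Cell Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies rotation of the embryonic zebrafish heart chambers
    around the atrioventricular (AV) canal from 3D+t cardiomyocyte tracks.
    Tracks are drift-stabilised by rooting the AV-canal centroid at the
    origin, each chamber is computationally "unfolded" by a per-frame rigid
    rotation about the AV hinge so its axis matches the first frame, and the
    residual per-cell rotation about the chamber axis is summarised as
    angular velocity, cumulative rotation angle and the atrium-ventricle
    twisting angle. Includes a seeded synthetic heart-tube track generator
    with known kinematics for parameter-recovery and confound testing,
    cell-shape morphometrics (roundness, boundary straightness, AV-canal
    angle) and tidy rank-sum/t-test group comparisons.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
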