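Package: tearfilm
Title: Quantitative Tear-Film Lipid Layer Thickness from White-Light
    Interference Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Measures the thickness of the precorneal tear-film lipid layer
    from eye videos recorded under broadband white illumination. A Fresnel
    multi-reflection thin-film interference model maps lipid thickness to the
    interference color seen by a CIE 1964 standard observer, producing a
    thickness-to-RGB lookup table. A six-phase video pipeline discards blink
    frames by global-brightness thresholding, locates the pupil and iris by
    seeded flood fill with blur refinement and orientation-filtered Canny
    edges, extracts a region of interest on the inferior iris, removes the
    iris color component and white-balances against the sclera, and assigns
    a thickness to every region-of-interest pixel by nearest color in the
    lookup table. Per-frame and pooled statistics, resampled surface grids
    and RGB scatter exports are produced, together with a fully labeled
    synthetic eye-video generator used for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
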