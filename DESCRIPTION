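Package: stereotrack
Title: 3D Particle Tracking from Two-Photon Stereo Projection Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs three-dimensional particle positions from parallax
    stereo-pair projection images acquired with extended-depth-of-field
    two-photon laser scanning stereomicroscopy, and links them into 3D
    trajectories over time. Includes image restoration (frequency-domain
    low-pass denoising and Richardson-Lucy deconvolution), adaptive-threshold
    segmentation with circular Hough transform particle detection, optimal
    (Hungarian) left-right stereo matching with disparity-to-depth conversion,
    frame-to-frame trajectory linking with gap closing, and trajectory
    analytics (mean squared displacement, drift velocity, localization
    precision, depth-error statistics). A built-in synthetic stereo-image
    simulator (Brownian motion with drift, diffraction blur, Poisson photon
    noise) makes every stage testable without a microscope.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    clue,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
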