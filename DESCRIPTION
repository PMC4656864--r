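Package: elmfit
Title: Ellipsoid Localization Microscopy for Fluorescent Shell Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers the size, shape, orientation and polar-localization bias of
    spheroidal fluorescent protein shells (such as bacterial spore coat layers)
    from widefield fluorescence micrographs, with precision well below the
    diffraction limit. Implements the closed-form image model of a thin
    spherical shell under a Gaussian point-spread function, Monte Carlo image
    models for stretched, uniform and polarized ellipsoidal shells, circular
    Hough segmentation of full frames, least-squares and iterative random-search
    fitting with sigma-based quality control, a calibration simulator with a
    defocus-dependent point-spread function and camera noise, and model-based
    superresolved reconstruction of the fitted shells.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
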