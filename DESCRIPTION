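Package: plotwave
Title: Plot Demarcation and Canopy Movement Quantification from Hemispherical Field Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for phenotyping wind-induced crop row movement from a
    stationary hemispherical (360 degree field of view) camera. A fiducial
    panel with a red square is located in a still frame to estimate the
    rotation between camera and field axes; a user-defined 2D field design is
    then projected through a spherical lens model onto pixel polygons that
    demarcate each plot. Panel-normalized red-channel waveforms extracted
    from those polygons are bandpass filtered, peak-analyzed into per-cycle
    frequencies and amplitudes, summarized into natural-frequency statistics
    and 0.2 Hz amplitude bins, and analyzed with a randomized-complete-block
    ANOVA using expected-mean-squares F tests and LSD mean separations.
    Includes a synthetic scene, video, waveform and field-trial generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
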