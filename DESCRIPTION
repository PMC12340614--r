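Package: speckleflow
Title: Diffuse Optical Blood-Flow Estimation with DCS, iDWS and SCOS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward models and processing pipelines for the three diffuse
    optical speckle techniques used to monitor deep-tissue blood flow:
    diffuse correlation spectroscopy (DCS), interferometric diffusing wave
    spectroscopy (iDWS) and speckle contrast optical spectroscopy (SCOS).
    Provides the semi-infinite correlation diffusion equation solution, the
    Siegert relation, the exposure-integrated speckle contrast model and
    Stokes-Einstein/Vogel phantom ground truth; a seeded detector-level
    synthetic speckle data generator (photon-count streams, line-scan
    interferograms, camera frame stacks); software correlators and model
    fits recovering the blood flow index (BFi) per modality; and
    cross-modality comparison tools (relative BFi, beat-averaged pulsatile
    waveforms, pulsatility index, nonparametric Bland-Altman, paired tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
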