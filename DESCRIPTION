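Package: nystcal
Title: Foveation-Based Eye-Tracker Calibration for Infantile Nystagmus
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Automated segmentation of uncalibrated infantile-nystagmus (IN)
    eye traces and foveation-based calibration of an eye tracker. Provides
    gap interpolation and blink trimming, Savitzky-Golay smoothing and
    differentiation of the gaze signal, scale-free cycle splitting and
    quick-phase detection, adaptive per-cycle foveation detection by
    lowest-mean-velocity window search, per-axis polynomial calibration with
    a cross-talk term, drift correction, post-calibration waveform metrics,
    and a seeded simulator of jerk and pendular nystagmus sessions with
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    signal,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
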