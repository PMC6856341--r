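Package: koopgait
Title: Koopman Spectral Analysis of Periodic Motion via Hankel Dynamic Mode
    Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Data-driven spectral analysis of periodic multi-channel angle
    recordings such as segmental elevation angles during walking. Implements
    exact and companion-matrix dynamic mode decomposition (DMD), row- and
    column-type Hankel (delay-embedding) DMD with Koopman eigenfunction and
    phase extraction, and an evaluation suite: variance accounted for,
    reconstruction error, DMD and Fourier spectra, harmonic-frequency
    deviation, a Fourier-average eigenfunction oracle, an SVD baseline and
    planar-deviation measures. Synthetic generators (double pendulum,
    harmonic gait signals, Van der Pol oscillator, linear systems) provide
    ground truth for verification.
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
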