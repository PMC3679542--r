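Package: iftmotion
Title: Intraflagellar Transport Kymography, Pause Statistics, and Optical-Trap
    Force Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of intraflagellar transport (IFT) and
    flagellar surface motility. Builds kymographs from fluorescence movies along
    straight or per-frame evolving flagellar paths, separates anterograde,
    retrograde and paused IFT trains by Fourier-space direction analysis (FSDA),
    localizes particles by two-dimensional Gaussian fitting, and computes the
    statistics that link train pausing to whole-cell gliding: pausing frequency,
    bead-train colocalization against a randomized null, pause-to-gliding lag
    times with exponential fits, and a Monte-Carlo independence test. Optical
    trap traces are analyzed for stiffness (equipartition), stall/release/escape
    event classification, peak forces, and viscous drag constants from
    exponential recoils and square-wave oscillation. A synthetic-data module
    simulates train injection, calcium-dependent pausing, bead coupling, gliding
    and bead-in-trap Langevin dynamics so every stage is testable end to end.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
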