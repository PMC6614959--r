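Package: needleforce
Title: Fourier-Series Modeling of Dynamic Needle-Insertion Forces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for modeling axial needle-insertion force recordings from
    percutaneous (biopsy) procedures. A finite Fourier series under periodic
    extension is fitted piecewise to phase-segmented force traces, with
    spectrum-based harmonic order selection, classical baseline models
    (polynomial, exponential, power law) for comparison, a raised-cosine
    respiratory organ-motion model, a synthetic multilayer tissue trace
    generator, and sample-accurate rendering of fitted models as a fixed-rate
    haptic force stream. Goodness of fit is summarised per phase as the
    coefficient of determination.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
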