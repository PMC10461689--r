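Package: hovmp
Title: Hill-of-Vision Volumetry for Microperimetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Volumetric analysis of macular microperimetry exams. Fits
    thin-plate-spline hill-of-vision surfaces to 24-point MAIA sensitivity
    grids and integrates them to total volume (VTOT) in cartesian
    (dB*deg^2) and polar (dB*sr) parameterizations, alongside classical
    metrics (mean sensitivity, 95% bivariate contour ellipse area).
    Includes Bland-Altman method comparison, nested linear mixed-effects
    association analysis with marginal and conditional R^2 and
    backward/forward variable selection, and a synthetic intermediate-AMD
    cohort generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    lme4,
    lmerTest,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
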