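Package: mrdeye
Title: Automated Marginal Reflex Distance (MRD1) Measurement from Infrared Eye Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures marginal reflex distance 1 (MRD1), the vertical distance
    from the pupil centre to the upper eyelid margin, from close-up infrared
    eye images. Provides a parameterized synthetic IR eye renderer with exact
    ground truth, a classical four-class segmenter (background, sclera, iris,
    pupil) with an injection path for external masks, calibrated geometry
    (Kasa pupil-circle fit, eyelid-margin localization, 5 mm fiducial-dot
    scaling), and the method-agreement statistics used in clinical validation
    of automated ptosis measurement: descriptives, one-way ANOVA with Scheffe
    post hoc (raw-data and moments-based), Pearson correlation, Bland-Altman
    limits of agreement, and simple linear regression, with tidy outputs and
    ggplot2 figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    ggplot2,
    rlang,
    generics,
    jsonlite,
    stats,
    utils,
    graphics,
    tools,
    EBImage,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
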