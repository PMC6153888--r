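Package: pathaniso
Title: Anisotropy of Traveled-Distance Estimation in the Sagittal Plane
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for distance-reproduction
    experiments probing whether path-integrated traveled distance is
    represented isotropically across translation directions in the sagittal
    plane. Provides motion-profile construction for target and test
    translations, a synthetic cohort generator with participant-level random
    variability and duration-strategy responders, participant and trial
    exclusion rules, five (an)isotropy error models fitted as nonlinear
    mixed-effects models and compared by small-sample corrected AIC, a body-
    versus earth-centered reference-frame correlation test, and a simulator
    stimulus-noise audit (signal-to-noise ratios and Weber-type differential
    thresholds).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nlme,
    withr,
    knitr
Config/testthat/edition: 3
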