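Package: riclpm
Title: Random-Intercept Cross-Lagged Panel Models by Full-Information
    Maximum Likelihood
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the longitudinal co-development of two
    repeatedly measured constructs (for example depressive symptom scores
    and a cardio-metabolic marker such as fat mass index) with uneven
    assessment schedules and substantial attrition. Provides a synthetic
    panel generator calibrated to a large birth-cohort setting, a cleaning
    pipeline (interquartile-range outlier masking, variance-stabilising
    transforms, min-max normalisation), from-scratch estimation of the
    lag-1 random-intercept cross-lagged panel model (RI-CLPM) and its
    autoregressive latent trajectory extension (ALT-SR) by full-information
    maximum likelihood over missingness patterns, standardized coefficients
    with Huber-White robust standard errors, RMSEA/CFI/TLI/SRMR fit
    evaluation, and time-adjusted (yearly) reporting of lagged effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
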