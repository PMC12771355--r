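Package: coagree
Title: Agreement and Trending Analysis for Cardiac Output Method Comparison
Version: 0.1.0
Authors@R: person("Repo", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Statistical validation toolkit for comparing a test cardiac-output
    monitor against a reference method (typically transthoracic
    echocardiography). Implements Doppler stroke-volume and cardiac-index
    derivation (Mosteller body surface area), Bland-Altman agreement analysis
    with bias, precision, limits of agreement, mean percentage error and their
    confidence intervals, robustness checks (Shapiro-Wilk normality,
    non-parametric percentile limits, repeated-measures variance-component
    correction, combined repeatability, mixed-effects proportional-bias
    regression), trending analysis (four-quadrant concordance with exclusion
    zone, polar-plot angular statistics), and a synthetic perioperative study
    generator with known ground truth for end-to-end testing and parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    lme4,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
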