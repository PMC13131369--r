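Package: mcmcteval
Title: Evaluation Framework for Multi-Camera Multi-Cow Tracking Systems
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for assessing camera-based cow monitoring systems in
    freestall dairy barns. Provides a synthetic herd-behavior generator
    (activities, barn zones, milking-robot visits on a fixed sampling grid),
    an emulator of multi-camera multi-cow tracking outputs under a
    configurable error model including discrete Frechet-distance trajectory
    identification, a hybrid detection-then-identification confusion-matrix
    framework with recall/precision/F1 metrics, finite-population sample-size
    calculations for on-farm validation campaigns, and an hourly
    detection-stability analysis based on a balanced hour-by-day
    variance-components model with Tukey-adjusted pairwise comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    emmeans,
    optparse
Config/testthat/edition: 3
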