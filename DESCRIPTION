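Package: gaitims
Title: Bilateral Temporal Gait Parameters from a Single In-Shoe Motion Sensor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Detects bilateral gait events (heel strike, toe off, opposite heel
    strike, opposite toe off and foot-flat) from the inertial signals of a single
    foot-mounted sensor using gradient-turning-point analysis based on the
    triangle thresholding algorithm. Computes temporal gait parameters of both
    lower limbs (double-support times, stance and stride times, signed symmetry
    indexes) with multi-stride averaging, and provides a method-comparison
    statistics pipeline (normality-gated bias tests, Bland-Altman limits of
    agreement with parametric and quantile-regression correction, ICC and
    Kendall's W). Includes a seedable synthetic gait simulator with exact
    ground-truth event annotations so every stage is testable without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    nortest,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
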