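Package: wheelergo
Title: Standardized and Individualized Wheelchair Ergometer Capacity Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of wheelchair roller-ergometer test batteries for
    anaerobic and aerobic capacity assessment. Processes 100 Hz torque and
    velocity traces from isometric strength, sprint, Wingate (WAnT) and
    graded exercise (GXT) tests; extracts the standard outcome scalars
    (F_iso, P30, P5, PO_peak, VO2peak and friends) with test-validity
    gating; derives individualized rolling-resistance settings for the
    WAnT and GXT from published and refitted prediction equations; and
    reconstructs the model-building procedure (univariate screening,
    collinearity pruning, backward elimination with sport dummy coding).
    A physics-based synthetic-data generator produces push-cycle traces,
    breath-by-breath records and athlete cohorts with known ground truth
    so the whole chain is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    zoo,
    stats,
    utils,
    tibble,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
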