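Package: turnwatch
Title: Turn-Protocol Compliance Analytics for Continual Patient Position Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to analyse continual patient-position monitoring data as
    used in pressure-injury prevention programmes. Provides a seeded
    simulator of wearable-sensor position traces (self-turns, scheduled
    caregiver turns with a tunable miss probability, sink-back angle drift,
    upright periods, documented exemption intervals, cohort demographics),
    a turn-detection and compliance engine implementing turn-period,
    turn-angle, decompression and grace-period rules with a three-colour
    bedside display state, pooled and per-patient compliance, 100-hour
    block adherence and hour-of-day compliance metrics, and a pre/post
    inferential toolkit (sample-size formula, two-sample t test, chi-square
    test of independence) wired into a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
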