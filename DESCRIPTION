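Package: rotpower
Title: Rotational Power from a Thigh-Worn Accelerometer in the 30-Second
    Chair Stand Test
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes rotational power (RP), an accelerometer-derived measure
    of sit-to-stand and stand-to-sit performance during the 30-second chair
    stand test, together with the motion-capture vertical-power reference
    branch used to validate it. Includes sensor-to-segment alignment via the
    Rodrigues rotation formula, zero-phase Bessel low-pass filtering,
    cross-correlation time synchronization between accelerometer and marker
    streams, transition segmentation and valid-repetition counting, the
    validation statistics used for analytical and clinical assessment of the
    metric (normality-gated correlations with Evans strength labels,
    two-way random-effects intraclass correlation for absolute agreement,
    95th-centile trial summaries, confounder-adjusted regression, and a
    three-window acute-fatigue analysis), and a ground-truthed synthetic
    session generator with closed-form kinematic oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    tools,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
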