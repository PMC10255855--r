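Package: fieldtriage
Title: Battlefield Casualty Triage from Body-Worn Biosignals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decision core for pre-hospital military casualty triage driven by
    wearable biosensors. Extracts continuous vital signs (heart rate,
    respiratory rate, oxygen saturation, cuffless systolic blood pressure via
    pulse arrival time, activity and posture) from multichannel ECG/PPG/
    respiration/accelerometer streams, applies a START-style rule cascade with
    degraded-mode reliability scoring when sensors drop out, calibrates a
    two-stage large-margin classifier into ordinal chance-of-survival bands,
    and maintains framed telemetry plus an append-only electronic casualty
    card. A seeded synthetic-physiology generator provides casualty scenarios
    with known ground truth for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
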