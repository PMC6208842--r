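Package: trajtask
Title: Timed Trajectory-Prediction Go/No-Go Task: Design, Simulation, and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a timed trajectory-prediction go/no-go experiment in
    which a stimulus moves from a fixation cross toward one of eight final
    locations inside or outside a visible target square, and the subject must
    touch the screen before stimulus arrival on go trials and withhold on
    no-go trials. Provides exact counterbalanced schedule generators for the
    trajectory task and a simple reaction-time task; a synthetic-subject
    simulator producing 200 Hz gaze, pupil, and hand traces with known
    ground-truth parameters; velocity-threshold saccade and hand-onset
    detection, gaze-stimulus tracking metrics, and automated trial quality
    control; task-evoked pupillary response outcomes (window means, slopes,
    peak size change, latency to peak); signal-detection analysis (hit and
    false-alarm rates, d-prime, criterion) and condition summaries; and
    normality-gated group comparison statistics with a reproducible
    end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
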