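Package: squatcoach
Title: Monitoring, Coaching and Adherence Analytics for Home Squat Exercises
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for monitoring home squat exercises from head-pose
    trajectories such as those tracked by an augmented-reality headset.
    Provides a synthetic squat-motion simulator with ground-truth labels,
    calibration and hysteresis-based repetition segmentation, per-repetition
    detection of depth, tempo and postural-deviation execution errors,
    five treatment-adherence dimensions (session, set and repetition
    completion rates plus temporal and spatial accuracy), a coaching message
    engine with behavior-change-technique tags, reminder scheduling and
    usage-based progression, and the evaluation statistics used in digital
    health studies (exact one-sample Wilcoxon signed-rank tests, one-sample
    t tests, Likert summaries and the Net Promoter Score).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
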