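Package: gericare
Title: Posture Monitoring, Movement-Habit Tracking and Care-Plan Decision
    Support for Geriatric Wards
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computational core of a camera-plus-wearable geriatric care
    monitoring workflow. Classifies postures from 17-keypoint 2D skeletons
    using geometric features, verifies each pose over a three-frame timed
    window, disambiguates lying from sleeping by fusing wristband heart-rate
    and sleep-state signals, accumulates a per-day activity ledger, detects
    multi-day movement-habit change from day-over-day percentage differences,
    recommends care-plan actions with an IF-THEN rule engine and a Gini
    impurity decision tree over a 21-variable patient state, re-identifies
    patients with a bag-of-visual-words image pipeline, and evaluates all
    classifiers with multiclass confusion, F1 and one-vs-rest ROC/AUC
    metrics. Ships synthetic generators for skeleton streams, vitals series,
    patient states and ward images so the whole pipeline runs without any
    private data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    png,
    e1071
Suggests:
    testthat (>= 3.0.0),
    rpart,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
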