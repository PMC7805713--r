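Package: lmaengage
Title: Automated Social-Engagement Measurement from Pose and Facial Keypoints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns 2D pose and facial keypoint streams (OpenPose-style, 25 body
    and 70 face points with confidences) and behavior-interval annotations
    (BORIS-style exports) into a quantitative social-engagement measure for
    child-robot interaction studies. Computes the three Laban Movement
    Analysis effort features (space, weight, time) from upper-body
    kinematics, derives a seven-level engagement index from six annotated
    target behaviors, assembles a 71-dimensional feature matrix, and trains
    personalized (per-subject) and group engagement classifiers: a native 1D
    convolutional network plus four classical baselines, evaluated with
    class-support-weighted metrics. Includes a synthetic cohort generator so
    the full pipeline is testable without access to the original recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    e1071,
    randomForest,
    rpart,
    class
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
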