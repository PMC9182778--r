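Package: skelwin
Title: Sliding-Window Skeleton Features for Fall Detection and Activity
    Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts per-frame human-pose skeletons (COCO 17-keypoint
    convention, AlphaPose result files) into fixed-length temporal feature
    vectors via sliding windows, labels each window by the statistical mode
    of its frame labels, trains and evaluates classical classifiers for
    binary fall detection and 12-class activity recognition, and performs
    an exhaustive search over window duration and skeletons-per-window to
    maximise cross-validated recall. Includes a synthetic skeleton-sequence
    generator with activity-specific temporal motifs so the full pipeline
    can be exercised without any video dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    randomForest,
    e1071,
    nnet,
    class,
    rpart
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
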