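Package: strokeAR
Title: Smartphone Activity Recognition for Persons with Stroke
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for recognising mobility-related activities (sitting, lying,
    standing, stair ascent/descent, walking) from waist-worn smartphone
    accelerometer, gyroscope and barometer streams, with an emphasis on
    gait-impaired stroke cohorts and lab-to-home generalisation. Provides a
    synthetic multi-sensor recording generator for healthy and stroke cohorts,
    multi-rate stream ingestion and resampling, sample-entropy edge trimming of
    phone-handling artifacts, overlapping-window segmentation, a 270-feature
    time/frequency catalogue, out-of-bag permutation feature ranking, a
    RUSBoost (random-undersampling AdaBoost.M2) classifier for imbalanced
    multiclass data with a random-forest baseline, and evaluation designs:
    leave-one-subject-out population models, gait-impairment stratification,
    environmental personal/global models with chronological folds, barometer
    ablation, subject-sample-size learning curves, and a paired t / ANOVA /
    Tukey / correlation test battery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    rpart,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
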