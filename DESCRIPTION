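Package: seizr
Title: Cross-Database Epileptic Seizure Detection from Long-Term EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Epoch-based detection of epileptic seizures in multi-channel
    scalp EEG, designed to transfer across recording databases. Recordings
    (EDF/EDF+) are split into 10-second per-channel epochs; two scalar
    features are extracted per epoch (the successive decomposition index and
    a log-compressed matrix determinant), per-channel rolling-median feature
    baselines are subtracted to cancel database-level offsets, and a
    radial-basis support vector machine classifies each epoch. Classifier
    output is smoothed with a 10-tap moving-average filter and thresholded
    into seizure events; reporting covers per-channel event counts, total
    seizure epochs, epoch-level sensitivity and specificity, and the event
    false-detection rate per hour. Includes a multi-database synthetic EEG
    generator with planted rhythmic seizures and a leave-one-database-out
    cross-validation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
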