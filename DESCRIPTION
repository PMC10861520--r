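Package: actiRA
Title: Digital Biomarkers of Rheumatoid Arthritis from Wrist-Worn Sensor Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline that turns remotely collected wearable sensor
    data and patient-reported outcomes into rheumatoid arthritis (RA) status
    and severity estimates. Includes a synthetic cohort generator with
    configurable group effects, activity recognition with hidden Markov model
    smoothing of per-epoch class posteriors, extraction of passive actigraphy
    features (activity volume, sleep, morning stiffness, night-time
    restlessness, fragmentation) and active guided-test features (wrist range
    of motion, walking, peg test, postural transitions), a univariate
    statistics and test-retest reliability suite, penalised classification
    and regression including the sparse-group lasso fitted by proximal
    gradient descent, subject-wise stratified cross-validation with
    majority-vote aggregation, and data-volume sufficiency experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nnet,
    signal,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    car,
    pROC
Config/testthat/edition: 3
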