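Package: toobert
Title: Trajectory-Order Pretraining for Coded Patient Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Self-supervised pretraining for coded longitudinal patient
    records (EHR trajectories). Augments masked-language-model pretraining of
    a small transformer encoder with a trajectory-order objective that learns
    to distinguish a patient's true visit/code ordering from permuted
    versions, using conditional code-swap (CCS) and visit-swap (CVS)
    weighting functions estimated from temporal co-occurrence counts.
    Includes a tidy data model for coded trajectories, cohort builders for
    onset and length-of-stay outcomes, a synthetic trajectory generator with
    planted directed transitions, and fine-tuning with a bidirectional GRU
    head and layer-wise learning-rate decay. The neural network, including
    backpropagation, is implemented in base R matrix code.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    jsonlite,
    withr,
    ggplot2,
    stats,
    utils,
    generics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    readr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
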