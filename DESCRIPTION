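Package: somnage
Title: Sleep EEG Brain Age, Hypoxic Burden, and CPAP Response Analytics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying brain aging from overnight polysomnography
    (PSG) and for analysing the longitudinal effect of continuous positive
    airway pressure (CPAP) therapy in obstructive sleep apnea (OSA). Implements
    a sleep-EEG preprocessing chain (contralateral mastoid referencing,
    sleep-latency trimming, zero-phase low-pass filtering, reference-channel
    artifact regression, 5-SD spike interpolation, bad-channel replacement,
    z-scoring), Morlet-wavelet scalogram construction binned to a fixed
    2000 x 16 x 7 model-input tensor, a trainable brain-age regressor contract
    with brain age index (BAI) arithmetic, SpO2 cleaning with apnea- and
    hypopnea-specific hypoxic-burden computation, respiratory event detection
    from airflow envelopes, longitudinal cohort statistics (paired tests,
    covariate-adjusted group comparison, FDR-controlled association scans),
    and CPAP-responder prediction via diagonal neighborhood component analysis
    feature weighting and a classifier battery under stratified
    cross-validation. A seeded synthetic PSG cohort generator provides the
    statistical structure the analysis assumes, so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    zoo,
    pracma,
    glmnet,
    nnet,
    rpart,
    randomForest,
    e1071,
    class,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
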