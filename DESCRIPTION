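Package: bpbeat
Title: Beat-to-Beat Cuffless Blood Pressure Estimation from ECG, BCG and PPG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for beat-to-beat cuffless blood pressure estimation from
    synchronized electrocardiogram (ECG), ballistocardiogram (BCG) and
    photoplethysmogram (PPG) recordings. Provides band-pass preprocessing,
    characteristic-point detection (Pan-Tompkins R peaks, BCG I/J fiducials,
    first-derivative PPG peaks), per-beat timing and amplitude feature
    extraction, a bidirectional LSTM sequence regressor with personal,
    leave-one-subject-out and fine-tuned training protocols, classical pulse
    transit time calibration baselines, and standards-based evaluation (BHS
    grading, AAMI criteria, Bland-Altman limits of agreement). A physics-based
    simulator generates synthetic multi-subject cohorts whose pulse transit
    timing is coupled to blood pressure through the Moens-Korteweg and Hughes
    relations, with per-beat ground-truth events for validating detectors.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
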