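Package: hrvdcan
Title: Heart Rate Variability and Autonomic Function Analysis for Early
    Cardiac Autonomic Neuropathy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.com",
    role = c("aut", "cre"))
Description: Short-term heart rate variability (HRV) analysis oriented to the
    detection of early cardiovascular autonomic neuropathy. Implements R-peak
    detection with parabolic refinement, rule-based cleaning of RR intervals to
    normal-to-normal (NN) series, time-domain indexes (pNN50+/-, RMSSD, SDNN
    index), Welch band powers of the 5-Hz resampled tachogram (VLF, LF, HF,
    total power, LF/HF), complexity indexes (sample entropy, multiscale entropy
    with fixed tolerance, multiscale detrended fluctuation analysis),
    ECG-derived respiration, transfer-function baroreflex sensitivity with
    LF-band coherency, scoring of the traditional autonomic function tests
    (Ewing battery, cold pressor, SCOPA-AUT), ROC/Youden classification
    utilities with false-discovery-rate correction, and a seeded synthetic-data
    generator emulating RR tachograms with prescribed band powers, respiratory
    QRS-amplitude modulation, baroreflex-coupled blood pressure, and
    two-group by two-condition index cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
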