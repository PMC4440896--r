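Package: telecg
Title: Automatic Single-Lead ECG Interpretation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automatic interpretation of short single-lead
    electrocardiogram records: band-pass FIR denoising and gradient-weighted
    baseline removal, R-peak detection with adaptive thresholding and
    search-back, PQRST fiducial delineation with Mexican-hat matched
    filtering, wavelet and peak-segment feature extraction, a hybrid
    classifier combining one-vs-rest radial-basis SVMs with a rule-based
    weighted-Bayesian premature-beat detector, beat-matching performance
    metrics, and a seeded synthetic arrhythmia ECG generator providing
    ground truth for every stage. Reads PhysioNet WFDB records and a plain
    CSV dialect with a JSON sidecar.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    e1071,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
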