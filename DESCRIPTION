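Package: kneeprop
Title: Exergame Knee Proprioception Analysis with IMU Calibration, Muscle
    Synergies, and Exact Rank Inference
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for exergame-based knee joint-position-sense
    training studies. Provides quaternion algebra and two-stage inertial
    sensor calibration for knee-angle estimation from thigh and shank
    orientation streams; encodings of squat (closed kinetic chain) and
    stretch (open kinetic chain) game protocols with angle-to-screen and
    sonification mappings; joint position error metrics (signed error,
    average mean error, improvement of error); z-score outlier screening;
    exact small-sample Mann-Whitney U inference via enumeration of the
    null rank distribution; EMG muscle-synergy extraction by non-negative
    matrix factorization with variance-accounted-for model selection; a
    noncentral-F power calculator for between-group repeated-measures
    designs; questionnaire scoring (intrinsic motivation and user
    experience instruments); and a synthetic cohort generator that
    emulates the full study design so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
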