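Package: autova
Title: Automated Visual Acuity Testing: Adaptive Exam Engine, Occluder Pose
    Validation, and Method-Agreement Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hardware-free implementation of a self-administered visual
    acuity (VA) testing workstation: a Snellen/logMAR chart model with
    per-letter (+/-) scoring, a state-driven adaptive examination engine
    (single-optotype descent, full-row confirmation, pinhole branch, per-eye
    sequencing), an occluder-pose validity engine driven by fiducial-marker ID
    sets and iris landmarks, vocabulary-constrained interpretation of speech
    transcripts with word-error-rate (WER) evaluation, a simulated-patient
    harness with a psychometric response model, and the clinical
    method-agreement statistics used to validate such systems (Bland-Altman
    limits of agreement, intraclass correlation, Wilcoxon signed-rank,
    Shapiro-Wilk, Spearman correlation, and outlier filtering).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
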