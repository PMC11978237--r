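Package: pelvicmotion
Title: Smartphone Versus Motion-Capture Pelvic Kinematics During Single-Leg Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for validating smartphone-derived
    pelvic kinematics against marker-based motion capture during single-leg
    squats and step-down exercises. Generates paired synthetic recordings
    (four-marker pelvis clusters at 250 Hz and smartphone
    acceleration/orientation logs at 100 Hz) from a shared ground-truth pelvis
    pose, processes both sensor branches to pelvic angles, displacement and
    mediolateral acceleration, segments repetitions from vertical displacement,
    extracts per-repetition outcomes (orientation at peak squat, mediolateral
    acceleration variability, repetition duration), and runs the full agreement
    analysis: normality-gated bias tests, two-way average-measures intraclass
    correlation with F-based confidence intervals, Bland-Altman limits of
    agreement, and between-task and between-group comparisons with
    Greenhouse-Geisser-corrected repeated-measures ANOVA or Friedman tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
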